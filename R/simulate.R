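# Deterministic, seeded generator of Helitron-like elements, host genomes
# and diverged genome pairs with truth tables. The defaults emulate the
# high-copy rice family: a ~2 kb non-autonomous element with 5' "TC", 3'
# "CTAG", a 16 bp GC-rich hairpin ending 13 bp upstream of the 3' end, a
# low-GC (~20 %) tandem Bloc A of six ~137 bp units and a ~40 % GC Bloc B
# of six ~152 bp units.

#' Specification of a synthetic Helitron-like element
#'
#' @param blocA,blocB Tandem bloc specs: lists with unit_length (bp),
#'   unit_count, gc (target GC fraction) and divergence (per-bp
#'   substitution rate of each unit copy relative to the bloc's unit
#'   consensus; Bloc B units are less conserved than Bloc A's).
#' @param bloc_order Order of the blocs 5' to 3'.
#' @param hairpin List with stem_len, loop_len (total = 2*stem + loop; the
#'   default 6 + 4 gives the canonical 16 bp) and offset_3p (bp from the
#'   hairpin's last base to the 3' terminal base, default 13).
#' @param termini Named character vector with five_prime (default "TC")
#'   and three_prime (default "CTAG", the family's CTRR instance).
#' @param target_length Total element length in bp (default 1993, the
#'   family consensus length); NULL keeps the anchor spacer layout
#'   (Bloc A starting near position 80, Bloc B near 950).
#' @param spacer_gc GC fraction of the non-repetitive spacers
#'   (default 0.30; the element is overall GC-poor).
#' @return A list of class \code{"element_spec"}.
#' @export
element_spec <- function(blocA = list(unit_length = 137L, unit_count = 6L,
                                      gc = 0.20, divergence = 0.02),
                         blocB = list(unit_length = 152L, unit_count = 6L,
                                      gc = 0.40, divergence = 0.05),
                         bloc_order = c("A", "B"),
                         hairpin = list(stem_len = 6L, loop_len = 4L,
                                        offset_3p = 13L),
                         termini = c(five_prime = "TC", three_prime = "CTAG"),
                         target_length = 1993L,
                         spacer_gc = 0.30) {
  stopifnot(setequal(bloc_order, c("A", "B")),
            hairpin$offset_3p > nchar(termini[["three_prime"]]),
            hairpin$offset_3p >= 5L, hairpin$offset_3p <= 35L,
            2L * hairpin$stem_len + hairpin$loop_len >= 15L,
            2L * hairpin$stem_len + hairpin$loop_len <= 20L)
  out <- as.list(environment())
  class(out) <- "element_spec"
  out
}

# One tandem bloc: unit_count copies of a fresh unit consensus, each copy
# independently diverged. The unit consensus carries the target GC exactly
# (shuffled fixed composition), so realized bloc GC stays within the
# mutational drift of the target.
render_bloc <- function(bloc) {
  if (bloc$unit_count < 1L) return("")
  n_gc <- round(bloc$gc * bloc$unit_length)
  bases <- c(sample(c("G", "C"), n_gc, replace = TRUE),
             sample(c("A", "T"), bloc$unit_length - n_gc, replace = TRUE))
  unit <- paste(sample(bases), collapse = "")
  paste(vapply(seq_len(bloc$unit_count), function(i)
    mutate_seq(unit, bloc$divergence), ""), collapse = "")
}

#' Generate a synthetic Helitron-like element
#'
#' Renders an element with the full canonical structure: 5' terminus,
#' spacer, tandem blocs, a GC-rich perfect stem-loop whose last base sits
#' exactly \code{offset_3p} bp upstream of the 3' terminal base, and the 3'
#' terminus. The generated hairpin is verified to be the one
#' [find_hairpin()] reports (the bases flanking the stem are fixed to
#' non-pairing As so the planted geometry is the unique optimum); the
#' element is re-drawn in the rare case a random spacer creates a better
#' competing stem-loop. Identical seeds give identical elements.
#'
#' @param spec See [element_spec()].
#' @param seed Integer seed; NULL uses (and advances) the current RNG
#'   stream.
#' @return The element as a character string with attributes \code{blocs}
#'   (data.frame label, start, end, unit_length, unit_count) and
#'   \code{hairpin} (list start, end, total_len, offset_3p).
#' @export
make_element <- function(spec = element_spec(), seed = NULL) {
  with_seed(seed, {
    tp <- spec$termini[["three_prime"]]
    fp <- spec$termini[["five_prime"]]
    hp_total <- 2L * spec$hairpin$stem_len + spec$hairpin$loop_len
    spacer3_len <- spec$hairpin$offset_3p - nchar(tp)
    for (try in 1:25) {
      blocs <- list(A = render_bloc(spec$blocA), B = render_bloc(spec$blocB))
      len_blocs <- sum(nchar(unlist(blocs)))
      fixed <- nchar(fp) + len_blocs + hp_total + spec$hairpin$offset_3p
      if (is.null(spec$target_length)) {
        s5 <- 77L; inter <- 48L; tailpad <- 103L
      } else {
        extra <- spec$target_length - fixed
        if (extra < 6L)
          stop("infeasible element spec: blocs and fixed structure need ",
               fixed + 6L, " bp, target is ", spec$target_length)
        s5 <- min(77L, max(2L, round(extra * 0.34)))
        inter <- min(48L, max(2L, round(extra * 0.21)))
        tailpad <- extra - s5 - inter
      }
      stem <- paste(sample(c("G", "C"), spec$hairpin$stem_len, replace = TRUE),
                    collapse = "")
      loop <- paste(sample(c("A", "T"), spec$hairpin$loop_len, replace = TRUE),
                    collapse = "")
      hairpin_seq <- paste0(stem, loop, reverse_complement(stem))
      tail_seq <- random_seq(tailpad, spec$spacer_gc)
      substr(tail_seq, tailpad, tailpad) <- "A"   # block outward stem extension
      spacer3 <- random_seq(spacer3_len, spec$spacer_gc)
      substr(spacer3, 1L, 1L) <- "A"
      segs <- c(fp, random_seq(s5, spec$spacer_gc),
                blocs[[spec$bloc_order[1L]]],
                random_seq(inter, spec$spacer_gc),
                blocs[[spec$bloc_order[2L]]],
                tail_seq, hairpin_seq, spacer3, tp)
      elem <- paste(segs, collapse = "")
      n <- nchar(elem)
      ends <- cumsum(nchar(segs))
      starts <- ends - nchar(segs) + 1L
      hp_start <- starts[7L]; hp_end <- ends[7L]
      hit <- find_hairpin(elem, n)
      if (is.null(hit) || hit$start != hp_start || hit$end != hp_end) next
      bloc_rows <- list()
      for (bi in 1:2) {
        lab <- spec$bloc_order[bi]
        seg_idx <- if (bi == 1L) 3L else 5L
        bspec <- if (lab == "A") spec$blocA else spec$blocB
        if (nchar(segs[seg_idx]) == 0L) next
        bloc_rows[[length(bloc_rows) + 1L]] <- data.frame(
          label = lab, start = starts[seg_idx], end = ends[seg_idx],
          unit_length = bspec$unit_length, unit_count = bspec$unit_count,
          stringsAsFactors = FALSE)
      }
      attr(elem, "blocs") <- if (length(bloc_rows)) do.call(rbind, bloc_rows)
        else data.frame(label = character(0), start = integer(0),
                        end = integer(0), unit_length = integer(0),
                        unit_count = integer(0), stringsAsFactors = FALSE)
      attr(elem, "hairpin") <- list(start = hp_start, end = hp_end,
                                    total_len = hp_total,
                                    offset_3p = spec$hairpin$offset_3p)
      return(elem)
    }
    stop("could not render an element whose planted hairpin is optimal")
  })
}

#' Size variant of an element sharing its termini
#'
#' Keeps the terminal regions of an element intact (at least the probe
#' lengths used in paired-termini scans) and replaces the interior with
#' random sequence to reach \code{target_length} -- the synthetic analogue
#' of structurally diverged family members, from short deletion
#' derivatives to multi-kb mother-element candidates that share only their
#' termini with the family.
#'
#' @param element Element string (e.g. from [make_element()]).
#' @param target_length Desired length in bp (>= 300).
#' @param keep Terminal length preserved on each side (default 200).
#' @param gc GC fraction of the random interior (default 0.35).
#' @return A character string of length \code{target_length}.
#' @export
element_size_variant <- function(element, target_length, keep = 200L,
                                 gc = 0.35) {
  n <- nchar(element)
  stopifnot(target_length >= 300L)
  keep <- min(keep, floor((target_length - 100L) / 2), floor((n - 10L) / 2))
  mid <- target_length - 2L * keep
  paste0(substr(element, 1L, keep), random_seq(mid, gc),
         substr(element, n - keep + 1L, n))
}

#' Plant elements into a random background genome
#'
#' Generates an i.i.d. background sequence at the target GC and inserts
#' each element at an A^T dinucleotide (between the A and the T), matching
#' the Helitron insertion-site rule; if no A^T exists within 100 bp of the
#' chosen position one is created (with a message). Elements are spaced at
#' least \code{min_spacing} apart and kept 1 kb from the sequence ends.
#'
#' @param genome_length Background length in bp (before insertions).
#' @param gc Background GC fraction (default 0.43, grass-genome scale).
#' @param elements Character vector/list of element sequences.
#' @param seed Integer seed; NULL uses the current RNG stream.
#' @param record_id Name of the generated sequence record.
#' @param min_spacing Minimum distance between planted elements (bp).
#' @return A list of class \code{"planted_genome"}: \code{genome} (named
#'   character vector) and \code{truth} (data.frame id, record_id, start,
#'   end, strand, length in final coordinates); the element strings (with
#'   their structural metadata) are attached to the truth table as
#'   attribute \code{"elements"}.
#' @export
plant_elements <- function(genome_length, gc = 0.43, elements, seed = NULL,
                           record_id = "synth_chr", min_spacing = 1000L) {
  elements <- as.list(elements)
  n <- length(elements)
  with_seed(seed, {
    bg <- random_seq(genome_length, gc)
    sites <- integer(0)
    if (n > 0L) {
      slot <- floor((genome_length - 2000L) / n)
      if (slot < min_spacing + 200L)
        stop("genome too small for ", n, " elements at >= ", min_spacing,
             " bp spacing")
      sites <- vapply(seq_len(n), function(i)
        as.integer(1000L + (i - 1L) * slot +
                     sample.int(slot - min_spacing, 1L)), 0L)
      # snap each site to an A^T dinucleotide (element goes between A and T)
      sites <- vapply(sites, function(p) {
        w_lo <- max(1L, p - 100L); w_hi <- min(genome_length - 1L, p + 100L)
        hit <- regexpr("AT", substr(bg, w_lo, w_hi), fixed = TRUE)
        if (hit > 0L) w_lo + as.integer(hit) - 1L
        else {
          message("no A^T near position ", p, "; creating one")
          substr(bg, p, p + 1L) <<- "AT"
          p
        }
      }, 0L)
    }
    parts <- character(0); pos <- 1L
    truth <- NULL
    offset <- 0L
    for (i in seq_len(n)) {
      j <- sites[i]
      parts <- c(parts, substr(bg, pos, j), as.character(elements[[i]]))
      st <- j + offset + 1L
      truth <- rbind(truth, data.frame(
        id = sprintf("ele_%03d", i), record_id = record_id,
        start = st, end = st + nchar(elements[[i]]) - 1L, strand = "+",
        stringsAsFactors = FALSE))
      offset <- offset + nchar(elements[[i]])
      pos <- j + 1L
    }
    parts <- c(parts, substr(bg, pos, genome_length))
    genome <- setNames(paste(parts, collapse = ""), record_id)
    if (is.null(truth))
      truth <- data.frame(id = character(0), record_id = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), stringsAsFactors = FALSE)
    truth$length <- if (nrow(truth)) interval_length(truth) else integer(0)
    attr(truth, "elements") <- elements
    out <- list(genome = genome, truth = truth)
    class(out) <- "planted_genome"
    out
  })
}

#' Divergence specification for a simulated genome pair
#'
#' Class counts mirror a comparative survey in which most inspected
#' candidate polymorphisms are repeat-number variants and only a few are
#' true insertion/excision events: defaults are 4 insertions, 4 excisions
#' (2 incomplete, 1 flank deletion, 1 filler), 120 repeat variants and 20
#' unchanged shared copies -- 148 loci in all.
#'
#' @param n_insertions New element insertions present in genome A only.
#' @param n_excisions Elements excised from genome B, with footprint mix
#'   \code{excision_mix} (named counts: incomplete, flank_deletion,
#'   filler; must sum to \code{n_excisions}).
#' @param excision_mix See above.
#' @param n_repeat_variants Shared elements whose bloc unit count changes
#'   by 1-3 units in genome B.
#' @param n_shared Shared elements left intact.
#' @param point_mutation_rate Per-bp substitution probability applied
#'   independently to both genomes (default 0.01, the order of neutral
#'   divergence between recently split rice species); must be in [0, 0.2].
#' @param residual_range,flank_del_range,filler_range Footprint geometry
#'   ranges in bp (uniform draws).
#' @return A list of class \code{"divergence_spec"}.
#' @export
divergence_spec <- function(n_insertions = 4L, n_excisions = 4L,
                            excision_mix = c(incomplete = 2L,
                                             flank_deletion = 1L,
                                             filler = 1L),
                            n_repeat_variants = 120L, n_shared = 20L,
                            point_mutation_rate = 0.01,
                            residual_range = c(30L, 300L),
                            flank_del_range = c(5L, 50L),
                            filler_range = c(5L, 200L)) {
  stopifnot(n_insertions >= 0L, n_excisions >= 0L, n_repeat_variants >= 0L,
            n_shared >= 0L, sum(excision_mix) == n_excisions,
            point_mutation_rate >= 0, point_mutation_rate <= 0.2)
  out <- as.list(environment())
  class(out) <- "divergence_spec"
  out
}

sample_range <- function(rng) {
  if (rng[1L] == rng[2L]) rng[1L]
  else rng[1L] + sample.int(rng[2L] - rng[1L] + 1L, 1L) - 1L
}

# Apply substitution edits to a sequence; returns the new sequence, the
# new-coordinate interval of each replacement, and an old->new position map
# for positions outside the edits.
apply_edits <- function(seq, edits) {
  n <- nchar(seq)
  if (is.null(edits) || nrow(edits) == 0L) {
    return(list(seq = seq, edits = edits,
                map = function(p) p))
  }
  edits <- edits[order(edits$old_start), , drop = FALSE]
  parts <- character(0); pos <- 1L
  cum <- 0L
  edits$new_start <- NA_integer_; edits$new_end <- NA_integer_
  new_len_before <- 0L
  for (i in seq_len(nrow(edits))) {
    s <- edits$old_start[i]; e <- edits$old_end[i]
    pre <- substr(seq, pos, s - 1L)
    parts <- c(parts, pre, edits$replacement[i])
    new_len_before <- new_len_before + nchar(pre)
    rl <- nchar(edits$replacement[i])
    edits$new_start[i] <- new_len_before + 1L
    edits$new_end[i] <- new_len_before + rl
    new_len_before <- new_len_before + rl
    cum <- cum + rl - (e - s + 1L)
    edits$cum_shift[i] <- cum
    pos <- e + 1L
  }
  parts <- c(parts, substr(seq, pos, n))
  shift_at <- edits$old_end
  shift_val <- edits$cum_shift
  list(seq = paste(parts, collapse = ""), edits = edits,
       map = function(p) {
         i <- findInterval(p - 0.5, shift_at)
         p + ifelse(i == 0L, 0L, shift_val[pmax(i, 1L)])
       })
}

# Modify a bloc's unit count in an element string by delta units.
vary_bloc_units <- function(elem, bloc_row, delta) {
  u <- bloc_row$unit_length
  bs <- bloc_row$start
  if (delta > 0L) {
    dup <- substr(elem, bs, bs + delta * u - 1L)
    paste0(substr(elem, 1L, bs - 1L), dup, substr(elem, bs, nchar(elem)))
  } else {
    cut <- -delta * u
    paste0(substr(elem, 1L, bs - 1L), substr(elem, bs + cut, nchar(elem)))
  }
}

#' Diverge a planted genome into a genome pair with truth table
#'
#' Genome A keeps every planted element and additionally receives
#' \code{n_insertions} new copies (clean A^T insertions, no target site
#' duplication). Genome B realizes the excisions (removing the element and
#' leaving the assigned footprint: a residual element fragment, a deletion
#' of adjacent flank, or random filler DNA), the repeat-number variants
#' (one bloc's unit count changed by 1-3 units) and the shared copies.
#' Independent point mutations are then applied to both genomes. The truth
#' table records every locus with its class and coordinates in both
#' genomes (empty sites have end = start - 1).
#'
#' @param planted A [plant_elements()] result; the number of planted
#'   elements must equal \code{n_excisions + n_repeat_variants +
#'   n_shared}.
#' @param spec See [divergence_spec()].
#' @param new_elements Character vector of length \code{n_insertions} with
#'   the elements to insert into genome A (typically diverged copies of
#'   the family archetype).
#' @param seed Integer seed; NULL uses the current RNG stream.
#' @return A list of class \code{"genome_pair"}: genome_a, genome_b (named
#'   character vectors), truth (data.frame locus_id, class, start_a,
#'   end_a, start_b, end_b, residual_bp, deleted_flank_bp, filler_bp,
#'   bloc_delta).
#' @export
diverge_pair <- function(planted, spec = divergence_spec(),
                         new_elements = NULL, seed = NULL) {
  truth <- planted$truth
  elements <- attr(truth, "elements")
  base <- planted$genome[[1L]]
  record_id <- names(planted$genome)[1L]
  needed <- spec$n_excisions + spec$n_repeat_variants + spec$n_shared
  if (nrow(truth) != needed)
    stop("planted genome has ", nrow(truth), " elements but the divergence ",
         "spec needs exactly ", needed,
         " (excisions + repeat variants + shared)")
  if (spec$n_insertions > 0L && length(new_elements) != spec$n_insertions)
    stop("need ", spec$n_insertions, " new_elements for the insertions")
  with_seed(seed, {
    classes <- sample(c(rep("excision_incomplete", spec$excision_mix[["incomplete"]]),
                        rep("excision_flank_deletion", spec$excision_mix[["flank_deletion"]]),
                        rep("excision_filler", spec$excision_mix[["filler"]]),
                        rep("repeat_variation", spec$n_repeat_variants),
                        rep("shared", spec$n_shared)))
    # --- genome B edits (footprints at excised/variant elements) ---
    b_edits <- NULL
    details <- data.frame(residual_bp = rep(NA_integer_, needed),
                          deleted_flank_bp = NA_integer_,
                          filler_bp = NA_integer_,
                          bloc_delta = NA_integer_)
    for (i in seq_len(needed)) {
      st <- truth$start[i]; en <- truth$end[i]
      elem <- as.character(elements[[i]])
      ed <- switch(classes[i],
        shared = NULL,
        excision_incomplete = {
          r <- sample_range(spec$residual_range)
          rs <- sample.int(nchar(elem) - r + 1L, 1L)
          details$residual_bp[i] <- r
          data.frame(old_start = st, old_end = en,
                     replacement = substr(elem, rs, rs + r - 1L),
                     stringsAsFactors = FALSE)
        },
        excision_flank_deletion = {
          d <- sample_range(spec$flank_del_range)
          details$deleted_flank_bp[i] <- d
          if (sample(c(TRUE, FALSE), 1L))
            data.frame(old_start = st - d, old_end = en, replacement = "",
                       stringsAsFactors = FALSE)
          else
            data.frame(old_start = st, old_end = en + d, replacement = "",
                       stringsAsFactors = FALSE)
        },
        excision_filler = {
          f <- sample_range(spec$filler_range)
          details$filler_bp[i] <- f
          data.frame(old_start = st, old_end = en,
                     replacement = random_seq(f, 0.5), stringsAsFactors = FALSE)
        },
        repeat_variation = {
          blocs <- attr(elem, "blocs") %||% attr(elements[[i]], "blocs")
          if (is.null(blocs) || nrow(blocs) == 0L)
            stop("repeat variation requested but element has no bloc metadata")
          bi <- sample.int(nrow(blocs), 1L)
          delta <- sample(c(-3:-1, 1:3), 1L)
          if (blocs$unit_count[bi] + delta < 2L)
            delta <- abs(delta)
          details$bloc_delta[i] <- delta
          data.frame(old_start = st, old_end = en,
                     replacement = vary_bloc_units(elem, blocs[bi, ], delta),
                     stringsAsFactors = FALSE)
        })
      if (!is.null(ed)) {
        ed$locus <- i
        b_edits <- rbind(b_edits, ed)
      }
    }
    b_res <- apply_edits(base, b_edits)
    # --- genome A edits (new insertions at fresh A^T sites) ---
    a_edits <- NULL
    if (spec$n_insertions > 0L) {
      n_base <- nchar(base)
      ins_sites <- integer(0)
      for (q in seq_len(spec$n_insertions)) {
        for (try in 1:200) {
          p <- 999L + sample.int(n_base - 1998L, 1L)
          clear <- all(abs(p - truth$start) > 1000L & abs(p - truth$end) > 1000L) &&
            (!length(ins_sites) || all(abs(p - ins_sites) > 1000L))
          if (!clear) next
          w_lo <- max(1L, p - 100L)
          hit <- regexpr("AT", substr(base, w_lo, p + 100L), fixed = TRUE)
          if (hit > 0L) { p <- w_lo + as.integer(hit) - 1L }
          else { substr(base, p, p + 1L) <- "AT" }
          # re-check spacing after the A^T snap
          if (all(abs(p - truth$start) > 900L & abs(p - truth$end) > 900L) &&
              (!length(ins_sites) || all(abs(p - ins_sites) > 900L))) {
            ins_sites <- c(ins_sites, p)
            break
          }
        }
      }
      if (length(ins_sites) < spec$n_insertions)
        stop("could not place all requested insertions")
      a_edits <- data.frame(old_start = ins_sites + 1L, old_end = ins_sites,
                            replacement = vapply(new_elements, as.character, ""),
                            locus = needed + seq_len(spec$n_insertions),
                            stringsAsFactors = FALSE)
    }
    a_res <- apply_edits(base, a_edits)
    # --- truth coordinates in both final genomes ---
    rows <- lapply(seq_len(needed), function(i) {
      st <- truth$start[i]; en <- truth$end[i]
      if (classes[i] %in% c("shared", "repeat_variation") ||
          is.null(b_edits) || !any(b_edits$locus == i)) {
        sb <- b_res$map(st - 1L) + 1L; eb <- b_res$map(en + 1L) - 1L
      } else {
        ed <- b_res$edits[b_res$edits$locus == i, ]
        sb <- ed$new_start; eb <- ed$new_end
      }
      data.frame(locus_id = truth$id[i], class = classes[i],
                 start_a = a_res$map(st), end_a = a_res$map(en),
                 start_b = sb, end_b = eb, stringsAsFactors = FALSE)
    })
    truth_tab <- cbind(do.call(rbind, rows), details)
    if (spec$n_insertions > 0L) {
      ed <- a_res$edits
      ins_rows <- lapply(seq_len(nrow(ed)), function(q) {
        site_b <- b_res$map(ed$old_end[q])
        data.frame(locus_id = sprintf("ins_%03d", q), class = "insertion",
                   start_a = ed$new_start[q], end_a = ed$new_end[q],
                   start_b = site_b + 1L, end_b = site_b,
                   residual_bp = NA_integer_, deleted_flank_bp = NA_integer_,
                   filler_bp = NA_integer_, bloc_delta = NA_integer_,
                   stringsAsFactors = FALSE)
      })
      truth_tab <- rbind(truth_tab, do.call(rbind, ins_rows))
    }
    genome_a <- mutate_seq(a_res$seq, spec$point_mutation_rate)
    genome_b <- mutate_seq(b_res$seq, spec$point_mutation_rate)
    out <- list(genome_a = setNames(genome_a, record_id),
                genome_b = setNames(genome_b, record_id),
                truth = truth_tab)
    class(out) <- "genome_pair"
    out
  })
}

#' Extract orthologous locus sequences from a simulated genome pair
#'
#' For each truth locus, extracts the element (or empty site) plus
#' \code{flank} bp of flanking sequence from both genomes.
#'
#' @param pair A [diverge_pair()] result.
#' @param flank Flank length in bp (default 500).
#' @return A data.frame with columns locus_id, class, seq_a, seq_b,
#'   suitable for [classify_loci()].
#' @export
orthologous_loci <- function(pair, flank = 500L) {
  a <- pair$genome_a[[1L]]; b <- pair$genome_b[[1L]]
  tr <- pair$truth
  ext <- function(s, st, en) {
    substr(s, max(1L, st - flank), min(nchar(s), en + flank))
  }
  data.frame(locus_id = tr$locus_id, class = tr$class,
             seq_a = vapply(seq_len(nrow(tr)), function(i)
               ext(a, tr$start_a[i], tr$end_a[i]), ""),
             seq_b = vapply(seq_len(nrow(tr)), function(i)
               ext(b, tr$start_b[i], tr$end_b[i]), ""),
             stringsAsFactors = FALSE)
}

#' One-call simulation of a diverged genome pair
#'
#' Generates a family archetype element, plants diverged copies of it into
#' a background genome sized to the requested locus counts, and produces
#' the genome pair with truth table. The family consensus (the archetype)
#' is attached for downstream classification.
#'
#' @param spec See [divergence_spec()].
#' @param espec See [element_spec()].
#' @param copy_divergence Per-bp substitution rate of each planted copy
#'   relative to the archetype (default 0.02, sub-type-scale divergence).
#' @param gc Background GC fraction.
#' @param seed Integer seed (required for reproducibility; every draw in
#'   the simulation derives from it).
#' @return A [diverge_pair()] result with an extra element
#'   \code{consensus} (the archetype sequence).
#' @export
simulate_pair <- function(spec = divergence_spec(), espec = element_spec(),
                          copy_divergence = 0.02, gc = 0.43, seed = 1L) {
  with_seed(seed, {
    arch <- make_element(espec)
    needed <- spec$n_excisions + spec$n_repeat_variants + spec$n_shared
    copies <- lapply(seq_len(needed), function(i) {
      cp <- mutate_seq(as.character(arch), copy_divergence)
      attributes(cp) <- attributes(arch)
      cp
    })
    glen <- max(20000L, needed * (nchar(arch) + 1500L) + 4000L)
    planted <- plant_elements(glen, gc = gc, elements = copies)
    new_elems <- replicate(spec$n_insertions, {
      cp <- mutate_seq(as.character(arch), copy_divergence)
      attributes(cp) <- attributes(arch)
      cp
    }, simplify = FALSE)
    pair <- diverge_pair(planted, spec, new_elements = new_elems)
    pair$consensus <- as.character(arch)
    pair
  })
}
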