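genome	chromosome	start_pos	end_pos	comment
O_sativa	11	26634911	26619399	Reverse
O_sativa	11	22184151	22168642	Reverse
O_sativa	11	24183680	24199188	Forward
O_sativa	5	592132	606965	Forward
O_sativa	5	25964570	25949203	Reverse
O_glaberrima	11	19460159	19467758	No RPA
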