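# Reference module and global connectance values reported for a C3 soybean
# (Glycine max) and a C4 palisade grass (Brachiaria brizantha) under three
# temperature conditions and two water regimes. cg_total_printed is the
# reported global value at the precision it was printed (printed_decimals);
# usable = FALSE marks the one cell whose printed total carries a last-digit
# discrepancy against the module values and is excluded from validation.
experiment,species,treatment,cg_pho,cg_ge,cg_total_printed,printed_decimals,usable,linking_printed
temperature,G.max,20C,1.68,1.22,1.45,2,TRUE,0.769
temperature,G.max,30C,1.82,2.31,2.06,2,TRUE,0.668
temperature,G.max,40C,2.42,2.65,2.54,2,TRUE,0.987
temperature,B.brizantha,20C,1.29,1.27,1.29,2,FALSE,0.591
temperature,B.brizantha,30C,0.88,1.35,1.12,2,TRUE,0.822
temperature,B.brizantha,40C,2.01,2.08,2.04,2,TRUE,0.953
water,G.max,100pct,4.09,1.28,2.7,1,TRUE,0.85
water,G.max,30pct,5.07,1.42,3.2,1,TRUE,0.97
water,B.brizantha,100pct,2.91,0.90,1.9,1,TRUE,0.31
water,B.brizantha,30pct,3.04,1.92,2.5,1,TRUE,0.93
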