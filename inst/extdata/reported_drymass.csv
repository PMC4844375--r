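# Reference total dry mass (DMt, g) reported for the same C3 soybean and C4
# palisade grass under the temperature and water-regime treatments; used to
# validate percent-change arithmetic against the benign reference cell
# (30C, 100pct refill).
experiment,species,treatment,DMt
temperature,G.max,20C,5.90
temperature,G.max,30C,12.97
temperature,G.max,40C,9.67
temperature,B.brizantha,20C,13.10
temperature,B.brizantha,30C,32.74
temperature,B.brizantha,40C,22.54
water,G.max,100pct,72.3
water,G.max,30pct,19.7
water,B.brizantha,100pct,147.7
water,B.brizantha,30pct,48.3
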