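# Published region-wide area bookkeeping (km2): per-class suitable areas
# and the occupied (AJO) / potentially occupied (APJO) totals.
quantity,km2
high,9017
medium,81473
marginal,114860
ajo,37825
apjo,16420
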