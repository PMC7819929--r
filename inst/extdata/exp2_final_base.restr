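restrict: D_ad.high = D_test.high = D_unknown.high = D_new.high
restrict: a1.high = g1.high
restrict: a2.high = g2.high
restrict: D_ad.low = D_test.low = D_unknown.low = D_new.low
restrict: a1.low = g1.low
restrict: a2.low = g2.low
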