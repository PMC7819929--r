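ad.high        ad        D_ad.high * d_ad.high
ad.high        ad        D_ad.high * (1-d_ad.high) * a1.high
ad.high        test      D_ad.high * (1-d_ad.high) * (1-a1.high) * a2.high
ad.high        unknown   D_ad.high * (1-d_ad.high) * (1-a1.high) * (1-a2.high)
ad.high        ad        (1-D_ad.high) * b.high * g1.high
ad.high        test      (1-D_ad.high) * b.high * (1-g1.high) * g2.high
ad.high        unknown   (1-D_ad.high) * b.high * (1-g1.high) * (1-g2.high)
ad.high        new       (1-D_ad.high) * (1-b.high)
test.high      test      D_test.high * d_test.high
test.high      ad        D_test.high * (1-d_test.high) * a1.high
test.high      test      D_test.high * (1-d_test.high) * (1-a1.high) * a2.high
test.high      unknown   D_test.high * (1-d_test.high) * (1-a1.high) * (1-a2.high)
test.high      ad        (1-D_test.high) * b.high * g1.high
test.high      test      (1-D_test.high) * b.high * (1-g1.high) * g2.high
test.high      unknown   (1-D_test.high) * b.high * (1-g1.high) * (1-g2.high)
test.high      new       (1-D_test.high) * (1-b.high)
unknown.high   unknown   D_unknown.high * d_unknown.high
unknown.high   ad        D_unknown.high * (1-d_unknown.high) * a1.high
unknown.high   test      D_unknown.high * (1-d_unknown.high) * (1-a1.high) * a2.high
unknown.high   unknown   D_unknown.high * (1-d_unknown.high) * (1-a1.high) * (1-a2.high)
unknown.high   ad        (1-D_unknown.high) * b.high * g1.high
unknown.high   test      (1-D_unknown.high) * b.high * (1-g1.high) * g2.high
unknown.high   unknown   (1-D_unknown.high) * b.high * (1-g1.high) * (1-g2.high)
unknown.high   new       (1-D_unknown.high) * (1-b.high)
new.high       new       D_new.high
new.high       ad        (1-D_new.high) * b.high * g1.high
new.high       test      (1-D_new.high) * b.high * (1-g1.high) * g2.high
new.high       unknown   (1-D_new.high) * b.high * (1-g1.high) * (1-g2.high)
new.high       new       (1-D_new.high) * (1-b.high)
ad.low         ad        D_ad.low * d_ad.low
ad.low         ad        D_ad.low * (1-d_ad.low) * a1.low
ad.low         test      D_ad.low * (1-d_ad.low) * (1-a1.low) * a2.low
ad.low         unknown   D_ad.low * (1-d_ad.low) * (1-a1.low) * (1-a2.low)
ad.low         ad        (1-D_ad.low) * b.low * g1.low
ad.low         test      (1-D_ad.low) * b.low * (1-g1.low) * g2.low
ad.low         unknown   (1-D_ad.low) * b.low * (1-g1.low) * (1-g2.low)
ad.low         new       (1-D_ad.low) * (1-b.low)
test.low       test      D_test.low * d_test.low
test.low       ad        D_test.low * (1-d_test.low) * a1.low
test.low       test      D_test.low * (1-d_test.low) * (1-a1.low) * a2.low
test.low       unknown   D_test.low * (1-d_test.low) * (1-a1.low) * (1-a2.low)
test.low       ad        (1-D_test.low) * b.low * g1.low
test.low       test      (1-D_test.low) * b.low * (1-g1.low) * g2.low
test.low       unknown   (1-D_test.low) * b.low * (1-g1.low) * (1-g2.low)
test.low       new       (1-D_test.low) * (1-b.low)
unknown.low    unknown   D_unknown.low * d_unknown.low
unknown.low    ad        D_unknown.low * (1-d_unknown.low) * a1.low
unknown.low    test      D_unknown.low * (1-d_unknown.low) * (1-a1.low) * a2.low
unknown.low    unknown   D_unknown.low * (1-d_unknown.low) * (1-a1.low) * (1-a2.low)
unknown.low    ad        (1-D_unknown.low) * b.low * g1.low
unknown.low    test      (1-D_unknown.low) * b.low * (1-g1.low) * g2.low
unknown.low    unknown   (1-D_unknown.low) * b.low * (1-g1.low) * (1-g2.low)
unknown.low    new       (1-D_unknown.low) * (1-b.low)
new.low        new       D_new.low
new.low        ad        (1-D_new.low) * b.low * g1.low
new.low        test      (1-D_new.low) * b.low * (1-g1.low) * g2.low
new.low        unknown   (1-D_new.low) * b.low * (1-g1.low) * (1-g2.low)
new.low        new       (1-D_new.low) * (1-b.low)
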