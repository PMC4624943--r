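# Hand-computed expectations for the 5-gene histone-stage fixture.
# References u1=u2=u3 give per-sample geometric means 3, 6, 2, 4; the
# control anchor is mean(2, 4) = 3, so the factors are 1, 2, 2/3, 4/3.
# canH normalized: 12, 12.5, 6, 6; varH floored to 0.1 then normalized:
# 0.1, 1, 4.5, 2.25. Fold change = ratio of group arithmetic means of the
# per-sample values; p from the two-sided Welch t-test on the same values.
set	fold_change	p_value
canonical	2.04166666666667	0.0254512226959837
variant	0.162962962962963	0.207570680222387
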