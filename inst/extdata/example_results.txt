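The intervention improved recall relative to control, t(85) = 2.86, p = .005,
and the interaction with condition was reliable, F(2, 120) = 3.41, p < .05.
Age correlated with accuracy, r(45) = .30, p = .04, while the association
with response time was not reliable, r(45) = .12, ns. A chi-squared test of
independence was significant, χ2(1, N = 320) = 5.02, p = .025, as was the
directional contrast, Z = 2.07, p = .04. A marginal effect was reported as
t(23) = 2.05, p = .05, and a clearly erroneous one as F(0, 55) = 3.10,
p = .02. No other statistics were reported in this article.
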