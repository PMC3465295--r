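# Central parameter objects shared across test files.
gp0 <- growth_params()          # W_inf 319, k 0.299, b 2.86, t0 anchored
cp0 <- conversion_params()      # beta 0.0328, 2.016 / 0.2 kJ/g WM, x10
mp0 <- metabolic_params()       # 0.8 x 0.8, total available 0.63

# trapezoid rule, independent of pracma, for oracle integrations
trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
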