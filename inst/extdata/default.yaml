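# Canonical assumption set for the ROSE-vs-fixed FNAB cost model.
#
# Units are encoded per symbol family:
#   t_*   : minutes            (t_setup, t_pass_fixed, t_pass_rose)
#   c_var*: currency per hour  (c_var_o = full non-cytologist team rate,
#                               c_var_c = cytologist rate)
#   c_pat : currency per hour  (patient wage, societal perspective only)
#   c_np  : currency per pass  (expected supplies + adverse-event cost)
#   c_fixed: currency per procedure
# Each parameter is {base, low, high}; [low, high] is the plausible range
# used by one-way and probabilistic sensitivity analysis.
#
# Procedure types: "simple" emulates palpation-guided office FNAB (short
# setup, small team; the cytologist performs the aspiration, so ROSE adds
# no personnel -> cytologist_in_fixed: true and both protocols bill the
# same hourly team rate, c_var_o + c_var_c = 130/hr). "complex" emulates
# image-guided procedures such as EUS-FNAB or CT-guided FNA (long setup,
# specialist team at 260/hr; ROSE adds the cytologist at 100/hr).
name: default
description: >
  Canonical base values and sensitivity ranges for the two procedure types
  and two per-pass adequacy levels.
shared:
  sn: {base: 0.95, low: 0.90, high: 1.00}
  sp: {base: 0.975, low: 0.95, high: 1.00}
  c_pat: {base: 20, low: 15, high: 25}
  t_pass_fixed: {base: 2, low: 1, high: 3}
  t_pass_rose: {base: 9, low: 6, high: 12}
adequacy:
  low:
    p: {base: 0.3, low: 0.2, high: 0.4}
  high:
    p: {base: 0.6, low: 0.5, high: 0.7}
procedure:
  simple:
    t_setup: {base: 4, low: 3, high: 5}
    c_var_o: {base: 30, low: 20, high: 40}
    c_var_c: {base: 100, low: 75, high: 125}
    c_np: {base: 0, low: 0, high: 0}
    c_fixed: {base: 150, low: 100, high: 200}
    cytologist_in_fixed: true
  complex:
    t_setup: {base: 30, low: 20, high: 30}
    c_var_o: {base: 260, low: 190, high: 330}
    c_var_c: {base: 100, low: 75, high: 125}
    c_np: {base: 30, low: 15, high: 45}
    c_fixed: {base: 300, low: 150, high: 450}
    cytologist_in_fixed: false
stopping:
  n_fixed: [2, 3, 4, 5]
  n_rose: [1, 2]
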