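# Alternate assumption set retained for comparison with the default:
# a more specific cytologist (sp = 0.99), shorter setup times (3 min
# simple, 20 min complex), and a direct hourly total of 310/hr for
# complex-procedure ROSE staffing (expressed as a rate override rather
# than the additive 260 + 100 composition). Same units and structure as
# default.yaml.
name: variant
description: >
  Alternate assumption set: higher cytologist specificity, shorter setup
  times, and a direct ROSE staffing total for complex procedures.
shared:
  sn: {base: 0.95, low: 0.90, high: 1.00}
  sp: {base: 0.99, low: 0.95, high: 1.00}
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
    t_setup: {base: 3, low: 3, high: 5}
    c_var_o: {base: 30, low: 20, high: 40}
    c_var_c: {base: 100, low: 75, high: 125}
    c_np: {base: 0, low: 0, high: 0}
    c_fixed: {base: 150, low: 100, high: 200}
    cytologist_in_fixed: true
  complex:
    t_setup: {base: 20, low: 20, high: 30}
    c_var_o: {base: 260, low: 190, high: 330}
    c_var_c: {base: 100, low: 75, high: 125}
    c_np: {base: 30, low: 15, high: 45}
    c_fixed: {base: 300, low: 150, high: 450}
    cytologist_in_fixed: false
    rose_rate_override: 310
stopping:
  n_fixed: [2, 3, 4, 5]
  n_rose: [1, 2]
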