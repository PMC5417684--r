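# Shared fixture builders; everything is generated in code at test time.

# mid-size phantom: wide enough for the default 250 x 450 ROI, fast to render
mid_phantom_spec <- function(seed = 1, apex_column = 256, ...) {
  phantom_spec(n_ascans = 512, n_axial = 700, apex_column = apex_column,
               seed = seed, ...)
}

# small phantom for mass property tests (too narrow for the default ROI)
random_small_spec <- function(seed) {
  set.seed(seed)
  phantom_spec(n_ascans = 200, n_axial = 600,
               cct_um = runif(1, 510, 600),
               epithelium_um = runif(1, 50, 60),
               anterior_radius_mm = runif(1, 7.3, 8.4),
               apex_column = sample(80:120, 1),
               apex_row = sample(80:130, 1),
               seed = seed)
}

cohort_candidates <- c("CCT", "CR", "AL", "ACD", "WTW", "age",
                       "GG_a", "GG_v", "GG_p", "GG_v_over_p")

table2_gg <- c(a = 0.287, v = 0.437, p = 2.80)
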