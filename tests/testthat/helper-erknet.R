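# shared test utilities and cached fixtures

# adjusted Rand index from the contingency table (no extra dependency)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}

# exhaustive warping-path DTW oracle: minimum over all boundary-anchored
# monotone paths, local cost |x_i - y_j|, diagonal cost doubled for
# symmetric2. Pure recursion over path extensions - independent of the DP
# implementation under test.
dtw_oracle <- function(x, y, symmetric2 = FALSE) {
  n <- length(x); m <- length(y)
  wd <- if (symmetric2) 2 else 1
  rec <- function(i, j) {
    d <- abs(x[i] - y[j])
    if (i == 1 && j == 1) return(d)
    best <- Inf
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1) + wd * d)
    if (i > 1) best <- min(best, rec(i - 1, j) + d)
    if (j > 1) best <- min(best, rec(i, j - 1) + d)
    best
  }
  rec(n, m)
}

# all integer-valued series over {0,1,2} up to a maximum length
all_int_series <- function(max_len, values = 0:2) {
  out <- list()
  for (len in seq_len(max_len))
    out <- c(out, asplit(as.matrix(expand.grid(
      rep(list(values), len), KEEP.OUT.ATTRS = FALSE)), 1))
  lapply(out, unname)
}

# cached expensive fixtures (built once per test run)
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

b3_truth <- function() cached("b3_truth", b3_reference_params())

suite_seed1 <- function()
  cached("suite_seed1", generate_training_suite(seed = 1, n_cells = 20))

ideal_suite_seed1 <- function()
  cached("ideal_suite_seed1", generate_ideal_suite(seed = 1))

# a generic well-behaved parameter set covering all 39 slots, used where the
# test only needs plausible dynamics rather than the committed B3 fixture
generic_params <- function(model) {
  full <- c(k1 = 0.05, k_1 = 0.3, k2 = 2, k_2 = 1, k3 = 0.5, k_3 = 2,
            HSPG_tot = 2, FGFR_tot = 1, w_FR = 0.1,
            k_act_Ras = 4, Km_Ras = 1, d_Ras = 1.5,
            k_act_Raf = 4, Km_Raf = 1, d_Raf = 1.5,
            k_act_MEK = 4, Km_MEK = 1, d_MEK = 1.5,
            k_act_ERK = 4, Km_ERK = 1, d_ERK = 1.5,
            NFB_tot = 1, k_nfb = 0.3, d_nfb = 0.15, K_inh = 0.3, h_nfb = 2,
            K_hfr = 0.5, h_hfr = 2, K_fgfr = 0.5, h_fgfr = 2,
            k_f = 3, Km_f = 1, k_r = 4, Km_r = 1, rho = 2, sigma = 0.05,
            a_pf = 1, K_pf = 0.3, h_pf = 2)
  full[model$params]
}

test_schedule <- function()
  make_schedule("multi_pulse", 25, width_min = 3, pause_min = 20,
                n_pulses = 3, total_min = 120)
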