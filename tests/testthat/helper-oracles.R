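# independent bisection oracle for the cycle-end equation
bisect_cycle_end <- function(laws, M, lower = 0, upper = NULL,
                             iter = 200) {
  n0 <- sum(vapply(laws, `[[`, numeric(1), "initial_count"))
  target <- 2^M * n0
  total_at <- function(t) sum(vapply(laws, function(l)
    if (t <= l$lag) l$initial_count
    else l$initial_count * 2^((t - l$lag) / l$doubling_time), numeric(1)))
  if (is.null(upper)) {
    upper <- max(vapply(laws, `[[`, numeric(1), "lag")) +
      2 * M * max(vapply(laws, `[[`, numeric(1), "doubling_time"))
  }
  for (i in seq_len(iter)) {
    mid <- (lower + upper) / 2
    if (total_at(mid) < target) lower <- mid else upper <- mid
  }
  (lower + upper) / 2
}

fps1_mutant <- function(n0 = 1) growth_law(276.6, 130.2, n0)
ask10_mutant <- function(n0 = 1) growth_law(503.3, 134.6, n0)
acr3_mutant <- function(n0 = 1) growth_law(630.4, 122.8, n0)
arsenic_wt <- function(n0 = 1e5 - 1) growth_law(804.8, 162.3, n0)
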