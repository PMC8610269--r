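# Independent oracles used across test files. These are deliberately naive
# (full enumeration, direct formula evaluation) and share no code with the
# package implementation.

# Exact two-sided rank-sum p-value by full enumeration of all C(m+n, m)
# assignments of ranks to the first group. Mirrors the two-sided convention
# p = min(1, 2 * tail probability) at the observed Mann-Whitney U.
# Tie-free inputs only.
enumerated_ranksum_p <- function(x, y) {
  m <- length(x); n <- length(y)
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_len(m)]) - m * (m + 1) / 2
  all_u <- apply(utils::combn(m + n, m), 2,
                 function(idx) sum(idx) - m * (m + 1) / 2)
  mu <- m * n / 2
  p <- if (u_obs > mu) 2 * mean(all_u >= u_obs) else 2 * mean(all_u <= u_obs)
  min(1, p)
}

# Product-limit estimator evaluated directly from its definition:
# S(t) = prod over event times t_i <= t of (1 - d_i / n_i).
product_limit <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- numeric(length(ut))
  cur <- 1
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    died <- sum(times == ut[i] & events == 1)
    cur <- cur * (1 - died / at_risk)
    s[i] <- cur
  }
  data.frame(time = ut, surv = s)
}

# Log partial likelihood for a single binary covariate, no ties (Breslow =
# Efron in that case), evaluated from the definition.
cox_logpl <- function(beta, times, events, x) {
  ord <- order(times)
  times <- times[ord]; events <- events[ord]; x <- x[ord]
  ll <- 0
  for (i in seq_along(times)) {
    if (events[i] == 1) {
      risk <- times >= times[i]
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
  }
  ll
}

# Quick noise-free simulated core with known ground truth.
noise_free_core <- function(stroma_conc = 0.305, epi_conc = 0.248,
                            seed = 11L, ...) {
  generate_core_image(image_sim_config(noise_sd = 0, bleedthrough = 0,
                                       stroma_cav1_conc = stroma_conc,
                                       epi_cav1_conc = epi_conc,
                                       seed = seed, ...))
}

# Tiny hand-built 4-channel image for mask-logic tests: a 6x6 grid where
# each marker mask is set explicitly.
grid_image <- function(dapi, vimentin, panck, cav1 = NULL, n = 6,
                       exposure = c(dapi = 100, vimentin = 100,
                                    panck = 100, cav1 = 100)) {
  as_ch <- function(m) {
    if (is.null(m)) matrix(0, n, n)
    else matrix(as.numeric(m), n, n)
  }
  structure(list(channels = list(dapi = as_ch(dapi),
                                 vimentin = as_ch(vimentin),
                                 panck = as_ch(panck), cav1 = as_ch(cav1)),
                 exposure_ms = exposure, core_id = "grid",
                 subject_id = "grid", roi_class = "tumor_stroma"),
            class = "multiplex_core_image")
}
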