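# Shared fixtures, all built in code.

# 3-item one-factor model: just identified with a mean structure,
# closed-form (tetrad) solution available.
tiny_battery <- function() item_battery(c("a", "b", "c"))
tiny_spec <- function() model_spec(tiny_battery(), list(F1 = c("a", "b", "c")))

# a random positive-definite 3x3 covariance consistent with a one-factor
# model (so the tetrad solution is admissible)
tiny_factor_cov <- function() {
  lam <- c(1, runif(1, 0.4, 1.5), runif(1, 0.4, 1.5))
  phi <- runif(1, 0.5, 2)
  th <- runif(3, 0.3, 1.2)
  S <- phi * tcrossprod(lam) + diag(th)
  dimnames(S) <- list(c("a", "b", "c"), c("a", "b", "c"))
  S
}

tetrad_solution <- function(S) {
  phi <- S[1, 2] * S[1, 3] / S[2, 3]
  lam <- c(1, S[2, 3] / S[1, 3], S[2, 3] / S[1, 2])
  list(phi = phi, lambda = lam, theta = diag(S) - lam^2 * phi)
}

# the published partial-uniqueness constraint profile of the CES-D analysis
cesd_partial_uniqueness_exemptions <- function() {
  rbind(data.frame(class = "intercept", item = c("Failure", "Good")),
        data.frame(class = "uniqueness",
                   item = c("Failure", "Good", "Depressed", "Fearful",
                            "Dislike")))
}

# two groups generated from identical parameters (full invariance holds)
null_genconfig <- function(n = c(500L, 500L)) {
  d <- default_cesd_params()
  generator_config(params = list(g1 = d$params$chinese,
                                 g2 = d$params$chinese),
                   sizes = c(g1 = n[1], g2 = n[2]), missing_rate = 0)
}

# small respondent-level Likert table for data-io tests
toy_items <- function(responses, battery = NULL, group = "g1") {
  if (is.null(battery))
    battery <- item_battery(colnames(responses))
  item_data(data.frame(group = group, responses, check.names = FALSE),
            battery)
}
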