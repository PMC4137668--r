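#' Left-brain-bias population mixture parameters
#'
#' The population mixes a low-risk majority whose language lateralization
#' is probabilistically biased to the left hemisphere (about 90:10) and a
#' high-risk minority with no bias (50:50). Risk -- not lateralization
#' itself -- also raises the probability of language impairment.
#'
#' @param p_risk Proportion of the population in the high-risk group.
#' @param bias_low P(left-lateralized | low risk), default 0.9.
#' @param bias_high P(left-lateralized | high risk), default 0.5.
#' @param p_impair_low,p_impair_high P(language impairment | group);
#'   defaults 0.05 and 0.5, with `p_impair_high >= p_impair_low`.
#' @return An object of class `population_params`.
#' @export
population_params <- function(p_risk = 0.2, bias_low = 0.9, bias_high = 0.5,
                              p_impair_low = 0.05, p_impair_high = 0.5) {
  p <- list(p_risk = p_risk, bias_low = bias_low, bias_high = bias_high,
            p_impair_low = p_impair_low, p_impair_high = p_impair_high)
  for (nm in names(p))
    if (!is.finite(p[[nm]]) || p[[nm]] < 0 || p[[nm]] > 1)
      stop(nm, " must be a probability in [0, 1]")
  if (p_impair_high < p_impair_low)
    stop("p_impair_high must be at least p_impair_low")
  structure(p, class = "population_params")
}

#' Expected proportion left-lateralized
#'
#' `P(left) = (1 - p_risk) * bias_low + p_risk * bias_high`, with the
#' per-group biases echoed.
#'
#' @param params A [population_params()].
#' @return List with `overall`, `low_risk`, `high_risk`.
#' @export
expected_laterality <- function(params) {
  list(overall = (1 - params$p_risk) * params$bias_low +
                 params$p_risk * params$bias_high,
       low_risk = params$bias_low, high_risk = params$bias_high)
}

#' Proportion of high-risk individuals with typical left lateralization
#'
#' With no bias in the high-risk group this is simply `bias_high`: even
#' carriers of the risk factor are left-lateralized half the time.
#'
#' @param params A [population_params()].
#' @return `bias_high`.
#' @export
expected_left_given_risk <- function(params) params$bias_high

#' Simulate individuals from the mixture
#'
#' Independent draws: risk group ~ Bernoulli(`p_risk`); laterality left
#' with the group's bias; impairment with the group's probability.
#'
#' @param n Number of individuals.
#' @param params A [population_params()].
#' @param seed Optional integer seed for reproducibility.
#' @return Data frame with logical columns `high_risk`, `left`, `impaired`.
#' @export
simulate_population <- function(n, params, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  risk <- stats::runif(n) < params$p_risk
  bias <- ifelse(risk, params$bias_high, params$bias_low)
  p_imp <- ifelse(risk, params$p_impair_high, params$p_impair_low)
  data.frame(high_risk = risk,
             left = stats::runif(n) < bias,
             impaired = stats::runif(n) < p_imp)
}

#' Twin concordance for laterality under shared risk group
#'
#' Co-twins share the risk group; laterality is drawn independently given
#' the group, so P(same side) for bias `b` is `b^2 + (1 - b)^2` -- exactly
#' 0.5 in the unbiased high-risk group (discordant as likely as
#' concordant), 0.82 at a 90:10 bias.
#'
#' @param params A [population_params()].
#' @return List with `low_risk`, `high_risk` concordance probabilities.
#' @export
twin_concordance <- function(params) {
  conc <- function(b) b^2 + (1 - b)^2
  list(low_risk = conc(params$bias_low), high_risk = conc(params$bias_high))
}

#' Expected and simulated case-control laterality tables
#'
#' Inverts the mixture by Bayes' rule to get P(high risk | impaired) and
#' P(high risk | not impaired), hence P(left) in each language-status
#' group, and returns the expected 2x2 (status x left/right) table for
#' given group sizes plus optional Monte-Carlo replicate tables (e.g. to
#' estimate the power of [linear_by_linear()]).
#'
#' @param params A [population_params()].
#' @param n_typical,n_impaired Group sizes.
#' @param n_replicates Number of Monte-Carlo replicate tables (default 0).
#' @param seed Optional integer seed.
#' @return List with `p_left` (per status), `expected`
#'   (a [contingency_table()] of expected counts, possibly non-integer,
#'   returned as a plain matrix), and `replicates` (list of
#'   [contingency_table()]s).
#' @export
expected_case_control_table <- function(params, n_typical, n_impaired,
                                        n_replicates = 0, seed = NULL) {
  stopifnot(n_typical >= 1, n_impaired >= 1)
  p_imp <- params$p_risk * params$p_impair_high +
           (1 - params$p_risk) * params$p_impair_low
  if (p_imp == 0 && n_impaired > 0)
    stop("impairment probability is zero in both groups")
  p_risk_imp <- params$p_risk * params$p_impair_high / p_imp
  p_noimp <- 1 - p_imp
  p_risk_typ <- params$p_risk * (1 - params$p_impair_high) / p_noimp
  p_left <- c(
    typical = p_risk_typ * params$bias_high + (1 - p_risk_typ) * params$bias_low,
    impaired = p_risk_imp * params$bias_high + (1 - p_risk_imp) * params$bias_low)
  expected <- rbind(typical = n_typical * c(p_left[["typical"]],
                                            1 - p_left[["typical"]]),
                    impaired = n_impaired * c(p_left[["impaired"]],
                                              1 - p_left[["impaired"]]))
  colnames(expected) <- c("left", "right")
  replicates <- list()
  if (n_replicates > 0) {
    if (!is.null(seed)) set.seed(seed)
    replicates <- lapply(seq_len(n_replicates), function(i) {
      lt <- stats::rbinom(1, n_typical, p_left[["typical"]])
      li <- stats::rbinom(1, n_impaired, p_left[["impaired"]])
      contingency_table(rbind(typical = c(lt, n_typical - lt),
                              impaired = c(li, n_impaired - li)),
                        col_labels = c("left", "right"))
    })
  }
  list(p_left = p_left, expected = expected, replicates = replicates)
}
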