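# Drug-effect libraries with receptor-class structure, and planted
# feature -> adverse-effect rules.

# Spread of log-multipliers in generated libraries: receptor-class centroids
# and within-class drug scatter. Their quadrature sum is the between-drug SD
# used to express planted effect sizes d in library units.
.sigma_class <- 0.15
.sigma_within <- 0.05
.sigma_irreg_class <- 0.02
.sigma_irreg_within <- 0.01

#' Between-drug spread of the synthetic library (log-multiplier scale)
#'
#' Planted rule effect sizes `d` are expressed in units of this SD, so
#' `d = 1` shifts an affected effect parameter by one between-drug standard
#' deviation.
#'
#' @return numeric scalar.
#' @export
library_sigma <- function() sqrt(.sigma_class^2 + .sigma_within^2)

.effect_params <- c("freq_mult", "amp_mult", "slope_mult", "velocity_mult")

#' Generate a synthetic drug library with receptor-class structure
#'
#' Each drug carries a per-tissue effect map (multipliers on slow-wave
#' frequency, amplitude, upstroke slope and propagation velocity, plus an
#' additive irregularity term). Drugs sharing a receptor class are drawn
#' around a shared class centroid, so within-class effect maps are closer
#' than between-class maps in expectation.
#'
#' @param n_drugs,n_classes counts, `1 <= n_classes <= n_drugs`.
#' @param seed integer seed; the library is a pure function of the
#'   arguments.
#' @return list of `drug_profile` objects (fields `drug_id`,
#'   `receptor_class`, `effects` data.frame with one row per tissue,
#'   `dose_scaling`).
#' @export
make_drug_library <- function(n_drugs, n_classes, seed) {
  assert_count(n_drugs, "n_drugs"); assert_count(n_classes, "n_classes")
  if (n_classes > n_drugs)
    stopf("invalid_argument", "n_classes (%d) exceeds n_drugs (%d)",
          n_classes, n_drugs)
  set.seed(derive_seed(seed, "drug_library", n_drugs, n_classes))
  n_t <- length(gi_tissues)
  centroids <- lapply(seq_len(n_classes), function(k) {
    list(logm = matrix(rnorm(n_t * length(.effect_params), 0, .sigma_class),
                       n_t, length(.effect_params),
                       dimnames = list(gi_tissues, .effect_params)),
         irreg = abs(rnorm(n_t, 0, .sigma_irreg_class)))
  })
  cls <- rep(seq_len(n_classes), length.out = n_drugs)
  lapply(seq_len(n_drugs), function(i) {
    cen <- centroids[[cls[i]]]
    logm <- cen$logm + matrix(rnorm(n_t * length(.effect_params), 0,
                                    .sigma_within),
                              n_t, length(.effect_params))
    irreg <- pmax(cen$irreg + rnorm(n_t, 0, .sigma_irreg_within), 0)
    eff <- as.data.frame(exp(logm))
    eff$irregularity_add <- irreg
    eff <- cbind(tissue = gi_tissues, eff)
    rownames(eff) <- NULL
    structure(list(drug_id = sprintf("drug_%03d", i),
                   receptor_class = sprintf("class_%02d", cls[i]),
                   effects = eff, dose_scaling = 1),
              class = "drug_profile")
  })
}

#' @export
print.drug_profile <- function(x, ...) {
  cat(sprintf("<drug_profile> %s (%s)\n", x$drug_id, x$receptor_class))
  print(x$effects, digits = 3)
  invisible(x)
}

#' Euclidean distance between two drug effect maps (log-multiplier space)
#'
#' @param a,b `drug_profile` objects.
#' @return numeric scalar.
#' @export
profile_distance <- function(a, b) {
  la <- log(as.matrix(a$effects[.effect_params]))
  lb <- log(as.matrix(b$effects[.effect_params]))
  sqrt(sum((la - lb)^2) + sum((a$effects$irregularity_add -
                                 b$effects$irregularity_add)^2))
}

#' Define a planted adverse-effect rule
#'
#' A rule marks a random fraction of drugs as positive for one AE and
#' perturbs their effect maps in stated directions, so the downstream
#' extractor and classifiers have a recoverable signal.
#'
#' @param ae_name adverse-effect name (canonical lower-case).
#' @param polarity `"excitatory"` or `"inhibitory"`; descriptive tag.
#' @param affected data.frame with columns `tissue`, `param` (one of
#'   `freq_mult`, `amp_mult`, `slope_mult`, `velocity_mult`,
#'   `irregularity_add`), `direction` (+1/-1) and `d` (> 0, effect size in
#'   units of [library_sigma()]).
#' @param prevalence fraction of drugs positive, in (0, 1).
#' @param indication_fraction fraction of positive drugs that additionally
#'   receive an indication row (exercising the indication override).
#' @return object of class `ae_rule`.
#' @export
ae_rule <- function(ae_name, polarity, affected, prevalence,
                    indication_fraction = 0) {
  if (prevalence < 0 || prevalence > 1)
    stopf("invalid_argument", "prevalence must be in [0,1]")
  if (any(affected$d <= 0))
    stopf("invalid_argument", "effect sizes d must be positive")
  if (!all(affected$tissue %in% gi_tissues))
    stopf("invalid_argument", "unknown tissue in rule")
  if (!all(affected$param %in% c(.effect_params, "irregularity_add")))
    stopf("invalid_argument", "unknown effect parameter in rule")
  structure(list(ae_name = tolower(ae_name),
                 polarity = match.arg(polarity,
                                      c("excitatory", "inhibitory")),
                 affected = affected, prevalence = prevalence,
                 indication_fraction = indication_fraction),
            class = "ae_rule")
}

#' Stock planted rules mirroring excitatory / inhibitory AE contrasts
#'
#' The excitatory rule raises colonic frequency and amplitude and lowers
#' stomach amplitude; the inhibitory rule lowers duodenal slope, amplitude
#' and frequency. These mirror the two contrast groups seen in real
#' feature-selection output (colon excitation vs duodenal inhibition).
#'
#' @param d effect size per affected parameter (units of [library_sigma()]).
#' @param prevalence fraction of drugs positive.
#' @param indication_fraction see [ae_rule()].
#' @return an `ae_rule`.
#' @export
excitatory_rule <- function(d = 1, prevalence = 0.5,
                            indication_fraction = 0) {
  ae_rule("excitatory_ae", "excitatory",
          data.frame(tissue = c("colon", "colon", "stomach"),
                     param = c("freq_mult", "amp_mult", "amp_mult"),
                     direction = c(1, 1, -1), d = d),
          prevalence, indication_fraction)
}

#' @rdname excitatory_rule
#' @export
inhibitory_rule <- function(d = 1, prevalence = 0.5,
                            indication_fraction = 0) {
  ae_rule("inhibitory_ae", "inhibitory",
          data.frame(tissue = "duodenum",
                     param = c("slope_mult", "amp_mult", "freq_mult"),
                     direction = -1, d = d),
          prevalence, indication_fraction)
}

#' Build a SIDER-style label table with planted rules
#'
#' For each rule, drugs are drawn positive with the rule's prevalence
#' (seeded), their effect maps are perturbed in the rule's stated
#' directions, and raw SIDER-style rows (`drug_id`, `ae_name`, `role`) are
#' emitted: one `side_effect` row per positive drug, plus an `indication`
#' row for the configured fraction of positives. Labels are then assigned
#' with the indication override (see [assign_labels()]).
#'
#' @param library list of `drug_profile` from [make_drug_library()].
#' @param rules list of `ae_rule`.
#' @param seed integer.
#' @return list with `labels` (an `ae_label_table`), `raw_rows`
#'   (data.frame) and `library` (the perturbed profiles actually simulated).
#' @export
make_ae_label_table <- function(library, rules, seed) {
  if (length(library) == 0) stopf("invalid_argument", "empty drug library")
  if (anyDuplicated(vapply(rules, function(r) r$ae_name, "")))
    stopf("invalid_argument", "rule AE names must be unique")
  drug_ids <- vapply(library, function(p) p$drug_id, "")
  raw <- list()
  for (rule in rules) {
    set.seed(derive_seed(seed, "ae_rule", rule$ae_name))
    # exact-count draw: the realized prevalence equals the rule's (up to
    # rounding), keeping planted datasets balanced by construction
    n_pos <- round(rule$prevalence * length(library))
    pos <- seq_along(library) %in% sample(length(library), n_pos)
    ind <- pos & (runif(length(library)) < rule$indication_fraction)
    shift <- library_sigma()
    for (i in which(pos)) {
      eff <- library[[i]]$effects
      for (k in seq_len(nrow(rule$affected))) {
        a <- rule$affected[k, ]
        row <- match(a$tissue, eff$tissue)
        if (a$param == "irregularity_add") {
          eff[row, a$param] <- pmax(eff[row, a$param] +
                                      a$direction * a$d * .sigma_irreg_class, 0)
        } else {
          eff[row, a$param] <- eff[row, a$param] * exp(a$direction * a$d * shift)
        }
      }
      library[[i]]$effects <- eff
    }
    if (any(pos))
      raw[[length(raw) + 1]] <- data.frame(drug_id = drug_ids[pos],
                                           ae_name = rule$ae_name,
                                           role = "side_effect")
    if (any(ind))
      raw[[length(raw) + 1]] <- data.frame(drug_id = drug_ids[ind],
                                           ae_name = rule$ae_name,
                                           role = "indication")
  }
  raw <- if (length(raw)) do.call(rbind, raw) else
    data.frame(drug_id = character(), ae_name = character(),
               role = character())
  labels <- assign_labels(raw, drug_ids,
                          vapply(rules, function(r) r$ae_name, ""))
  list(labels = labels, raw_rows = raw, library = library)
}
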