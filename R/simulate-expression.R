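#' Simulate a two-class expression cohort with a planted signature
#'
#' Generates a log2-scale genes x samples matrix in which a chosen subset
#' of genes differs between chemosensitive and chemoresistant samples by
#' a planted log2 fold change; all other genes share the same class
#' means. Defaults mirror the 232-sample serous ovarian carcinoma
#' training cohort (67 of 232 chemoresistant); the gene-space size is a
#' desk-scale choice.
#'
#' Planted genes split into \code{n_up} genes up-regulated in the
#' sensitive class (positive signal-to-noise ratio) and the remainder
#' up-regulated in the resistant class. Baseline per-gene means are drawn
#' once from N(7, 1.5^2), typical of log2 microarray intensities.
#'
#' @param n_samples number of samples.
#' @param n_genes number of genes.
#' @param n_informative number of planted differential genes
#'   (<= n_genes).
#' @param log2_fold_change planted between-class difference, log2 units.
#' @param noise_sd per-observation Gaussian noise SD, log2 units.
#' @param resistant_fraction fraction of samples labelled resistant.
#' @param n_up number of informative genes higher in the sensitive
#'   class; default half (rounded up).
#' @param seed integer seed.
#'
#' @return list with \code{matrix} (genes x samples, dimnames set),
#'   \code{labels} (named character vector, "sensitive"/"resistant") and
#'   \code{truth}: list with \code{informative} gene ids,
#'   \code{direction} (+1 higher in sensitive, -1 higher in resistant,
#'   named by gene), \code{log2_fold_change}, \code{noise_sd},
#'   \code{seed}.
#' @export
simulate_expression <- function(n_samples = 232L,
                                n_genes = 2000L,
                                n_informative = 50L,
                                log2_fold_change = 1,
                                noise_sd = 0.5,
                                resistant_fraction = 67 / 232,
                                n_up = ceiling(n_informative / 2),
                                seed = 1L) {
  stopifnot(n_informative <= n_genes, n_up <= n_informative,
            noise_sd > 0, n_samples >= 2)
  n_res <- round(resistant_fraction * n_samples)
  if (n_res < 1L || n_res > n_samples - 1L)
    stop("resistant_fraction leaves an empty class")

  with_seed(seed, {
    genes <- sprintf("gene_%05d", seq_len(n_genes))
    samples <- sprintf("sample_%03d", seq_len(n_samples))
    labels <- rep("sensitive", n_samples)
    labels[sample.int(n_samples, n_res)] <- "resistant"
    names(labels) <- samples

    base <- rnorm(n_genes, mean = 7, sd = 1.5)
    mat <- matrix(rnorm(n_genes * n_samples, sd = noise_sd),
                  nrow = n_genes, dimnames = list(genes, samples))
    mat <- mat + base

    informative <- sample(genes, n_informative)
    direction <- rep(c(1, -1), c(n_up, n_informative - n_up))
    names(direction) <- informative
    is_sens <- labels == "sensitive"
    half <- log2_fold_change / 2
    for (g in informative) {
      mat[g, is_sens]  <- mat[g, is_sens]  + direction[g] * half
      mat[g, !is_sens] <- mat[g, !is_sens] - direction[g] * half
    }

    list(matrix = mat, labels = labels,
         truth = list(informative = informative, direction = direction,
                      log2_fold_change = log2_fold_change,
                      noise_sd = noise_sd, seed = as.integer(seed)))
  })
}

#' Simulate survival times with a planted hazard ratio
#'
#' Event times are exponential: sensitive samples have rate
#' log(2)/\code{baseline_median}; resistant samples have that rate
#' multiplied by \code{hazard_ratio}, so proportional hazards hold
#' exactly and the resistant median is \code{baseline_median /
#' hazard_ratio}. Censoring times are independent Uniform(0, u) with u
#' calibrated so the expected censored fraction equals
#' \code{censoring_fraction}. Defaults reflect the printed
#' progression-free survival structure of the cohort (sensitive median
#' 25.8 months, resistant 9.3, ratio about 2.8).
#'
#' @param labels named character vector of "sensitive"/"resistant".
#' @param hazard_ratio resistant-vs-sensitive hazard ratio (> 0).
#' @param baseline_median median event time of the sensitive class,
#'   months.
#' @param censoring_fraction expected fraction of censored records in
#'   \[0, 1).
#' @param seed integer seed.
#'
#' @return data.frame with columns \code{sample_id}, \code{group},
#'   \code{time} (months), \code{event} (1 = event observed, 0 =
#'   censored).
#' @export
simulate_survival <- function(labels,
                              hazard_ratio = 2.8,
                              baseline_median = 25.8,
                              censoring_fraction = 0.3,
                              seed = 1L) {
  labels <- check_labels(labels)
  stopifnot(hazard_ratio > 0, baseline_median > 0,
            censoring_fraction >= 0, censoring_fraction < 1)
  n <- length(labels)
  rate0 <- log(2) / baseline_median
  rate <- ifelse(labels == "resistant", rate0 * hazard_ratio, rate0)

  with_seed(seed, {
    t_event <- rexp(n, rate)
    if (censoring_fraction == 0) {
      time <- t_event; event <- rep(1L, n)
    } else {
      # P(censored | rate l, C ~ U(0,u)) = (1 - exp(-l u)) / (l u);
      # calibrate u on the label mix.
      p_res <- mean(labels == "resistant")
      pc <- function(u) {
        f <- function(l) (1 - exp(-l * u)) / (l * u)
        (1 - p_res) * f(rate0) + p_res * f(rate0 * hazard_ratio)
      }
      u <- uniroot(function(u) pc(u) - censoring_fraction,
                   lower = 1e-6, upper = 1e6, tol = 1e-9)$root
      t_cens <- runif(n, 0, u)
      event <- as.integer(t_event <= t_cens)
      time <- pmin(t_event, t_cens)
    }
    data.frame(sample_id = if (is.null(names(labels)))
                 sprintf("sample_%03d", seq_len(n)) else names(labels),
               group = labels, time = time, event = event,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a clinical table (survival endpoints plus covariates)
#'
#' Builds the clinical table consumed by the survival stage: overall and
#' progression-free survival per sample, plus age, FIGO stage and WHO
#' grade drawn from the marginal distributions of the 253-patient serous
#' ovarian carcinoma cohort (mean age 59.9, SD 11.4; stages II/III/IV at
#' 13/203/37; grades 2/3 at 37/211 excluding unknowns).
#'
#' @param labels named character vector of "sensitive"/"resistant".
#' @param pfs_hazard_ratio,os_hazard_ratio planted hazard ratios.
#' @param pfs_baseline_median,os_baseline_median sensitive-class medians
#'   in months (printed cohort values: PFS 25.8, OS 53.9).
#' @param censoring_fraction expected censored fraction per endpoint.
#' @param seed integer seed.
#' @return data.frame with columns sample_id, response, os_months,
#'   os_event, pfs_months, pfs_event, age, stage, grade.
#' @export
simulate_clinical <- function(labels,
                              pfs_hazard_ratio = 2.8,
                              os_hazard_ratio = 1.6,
                              pfs_baseline_median = 25.8,
                              os_baseline_median = 53.9,
                              censoring_fraction = 0.3,
                              seed = 1L) {
  labels <- check_labels(labels)
  n <- length(labels)
  pfs <- simulate_survival(labels, pfs_hazard_ratio, pfs_baseline_median,
                           censoring_fraction, seed = seed + 1L)
  os <- simulate_survival(labels, os_hazard_ratio, os_baseline_median,
                          censoring_fraction, seed = seed + 2L)
  with_seed(seed + 3L, {
    data.frame(sample_id = pfs$sample_id, response = labels,
               os_months = os$time, os_event = os$event,
               pfs_months = pfs$time, pfs_event = pfs$event,
               age = round(rnorm(n, 59.9, 11.4), 1),
               stage = sample(c("II", "III", "IV"), n, replace = TRUE,
                              prob = c(13, 203, 37)),
               grade = sample(c("2", "3"), n, replace = TRUE,
                              prob = c(37, 211)),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a morphologic feature matrix with a planted signature
#'
#' Generates a samples x features matrix on the normalized (log,
#' median-centred) scale with the correlation structure characteristic
#' of binned nuclear profiles: a latent per-sample factor (overall
#' nuclear size/shape scale) loads on every feature, so features are
#' strongly inter-correlated, as the image-to-profile chain itself
#' produces (a dominant principal component carrying roughly half the
#' variance). A planted subset of features is shifted between the two
#' response classes: \code{n_up} features higher in the sensitive class
#' (positive signal-to-noise ratio) and the rest higher in the
#' resistant class.
#'
#' @param n_samples number of samples (cohort default 130, the
#'   training-set size: 90 sensitive / 40 resistant).
#' @param n_features number of features (153, the profile size).
#' @param n_informative planted differential features.
#' @param n_up planted features favoring the sensitive class.
#' @param shift planted between-class difference.
#' @param noise_sd independent per-feature noise SD.
#' @param loading_range range of latent-factor loadings (uniform).
#' @param resistant_fraction fraction of resistant samples.
#' @param seed integer seed.
#' @return list(features — samples x features data.frame, labels,
#'   truth — list(informative, direction, shift, seed)).
#' @export
simulate_feature_matrix <- function(n_samples = 130L,
                                    n_features = 153L,
                                    n_informative = 15L,
                                    n_up = 5L,
                                    shift = 1,
                                    noise_sd = 0.5,
                                    loading_range = c(0.4, 1),
                                    resistant_fraction = 40 / 130,
                                    seed = 1L) {
  stopifnot(n_informative <= n_features, n_up <= n_informative)
  n_res <- round(resistant_fraction * n_samples)
  if (n_res < 2L || n_res > n_samples - 2L)
    stop("resistant_fraction leaves a class too small")
  with_seed(seed, {
    feats <- sprintf("feat_%03d", seq_len(n_features))
    samples <- sprintf("sample_%03d", seq_len(n_samples))
    labels <- rep("sensitive", n_samples)
    labels[sample.int(n_samples, n_res)] <- "resistant"
    names(labels) <- samples
    z <- rnorm(n_samples)
    lam <- runif(n_features, loading_range[1], loading_range[2])
    m <- outer(lam, z) +
      matrix(rnorm(n_features * n_samples, 0, noise_sd), n_features)
    dimnames(m) <- list(feats, samples)
    informative <- sample(feats, n_informative)
    direction <- rep(c(1, -1), c(n_up, n_informative - n_up))
    names(direction) <- informative
    is_sens <- labels == "sensitive"
    m[informative, is_sens] <- m[informative, is_sens] +
      direction * shift / 2
    m[informative, !is_sens] <- m[informative, !is_sens] -
      direction * shift / 2
    list(features = as.data.frame(t(m)), labels = labels,
         truth = list(informative = informative, direction = direction,
                      shift = shift, seed = as.integer(seed)))
  })
}
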