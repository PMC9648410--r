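#' Synthetic cohort generator configuration
#'
#' Parameters of the seeded cohort generator. A latent per-sample
#' replication-stress factor drives (i) expression of planted signature
#' genes (two of them with negative loadings, exercising the
#' POLD4/POLE4-like sign behaviour), (ii) the four characteristic
#' variables on the scales of their published cutoffs, (iii) drug
#' activities by class, and (iv) the survival hazard. Defaults emulate
#' the derivation study conditions: 60 samples (near the 67-line
#' derivation panel), 2000 genes, two "signal" mock hallmark sets that
#' both carry the 11 planted leading-edge genes plus disjoint filler,
#' and decoy sets drawn from unloaded genes.
#'
#' @param n_samples Number of samples (default 60).
#' @param n_genes Total genes (default 2000).
#' @param signal_loading Latent-factor loading of the planted
#'   leading-edge genes, in units of the noise sd (default 1.5: a
#'   strong planted effect).
#' @param repair_loading Loading magnitude of the 7 planted repair
#'   genes; POLD4 and POLE4 get the negative sign (default 1).
#' @param ne_loading Loading magnitude of the 25 high-NE (positive) and
#'   25 low-NE (negative) genes (default 0.8).
#' @param noise_sd Residual expression noise sd (default 1).
#' @param n_sets Total mock hallmark sets including the two signal sets
#'   (default 50, the size of the usual hallmark collection).
#' @param set_size Members per set (default 35).
#' @param drug_loading Latent loading of replication-stress-targeting
#'   drug activities; MAPK-like drugs get the opposite sign (default 1).
#' @param n_drugs_per_class Drugs per class (default 10).
#' @param baseline_hazard Exponential baseline hazard for survival
#'   simulation (default 0.1 events per time unit).
#' @param survival_beta Log hazard ratio per unit latent factor
#'   (default `log(2)`).
#' @param censor_max Upper limit of uniform censoring times
#'   (default 30).
#' @param seed Integer seed (required; every draw depends on it).
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 60, n_genes = 2000,
                          signal_loading = 1.5, repair_loading = 1,
                          ne_loading = 0.8, noise_sd = 1,
                          n_sets = 50, set_size = 35,
                          drug_loading = 1, n_drugs_per_class = 10,
                          baseline_hazard = 0.1,
                          survival_beta = log(2), censor_max = 30,
                          seed) {
  if (missing(seed)) stop("seed is required")
  lists <- repstress_gene_lists()
  n_named <- length(lists$leading_edge) + length(lists$ne_repair) + 50
  if (n_genes < n_named + n_sets * set_size)
    stop("n_genes too small for the requested gene sets")
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 signal_genes = lists$leading_edge,
                 repair_genes = lists$ne_repair,
                 negative_genes = c("POLD4", "POLE4"),
                 signal_loading = signal_loading,
                 repair_loading = repair_loading,
                 ne_loading = ne_loading, noise_sd = noise_sd,
                 n_sets = n_sets, set_size = set_size,
                 drug_loading = drug_loading,
                 n_drugs_per_class = n_drugs_per_class,
                 baseline_hazard = baseline_hazard,
                 survival_beta = survival_beta,
                 censor_max = censor_max,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a characterized cohort with a planted latent factor
#'
#' Draws a standard-normal latent replication-stress factor per sample
#' and generates, as deterministic functions of the configuration and
#' seed: a genes x samples log-scale expression matrix
#' (`baseline + loading * factor + noise`), copy-number, drug-activity
#' and RPPA annotation tables calibrated so the published cutoffs
#' (0.7, 6, 0.15) split the cohort non-trivially, disjoint 25-gene
#' high/low NE sets loaded positively/negatively on the factor, a mock
#' hallmark collection in which exactly two "signal" sets carry the 11
#' planted leading-edge genes (with disjoint filler members), and a
#' truth record.
#'
#' @param cfg A [cohort_config()].
#' @return List with `expr`, `cn`, `drug`, `rppa`, `sets`,
#'   `ne_high_set`, `ne_low_set`, `truth` (list: `factor`, `loadings`,
#'   `signal_sets`, `signal_genes`, `negative_genes`) and `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  f <- stats::rnorm(n)

  ne_high <- sprintf("NEH%02d", 1:25)
  ne_low <- sprintf("NEL%02d", 1:25)
  named <- c(cfg$signal_genes, cfg$repair_genes, ne_high, ne_low)
  filler <- sprintf("G%04d", seq_len(cfg$n_genes - length(named)))
  genes <- c(named, filler)

  loadings <- stats::setNames(numeric(length(genes)), genes)
  loadings[cfg$signal_genes] <- cfg$signal_loading
  loadings[cfg$repair_genes] <- cfg$repair_loading
  loadings[cfg$negative_genes] <- -cfg$repair_loading
  loadings[ne_high] <- cfg$ne_loading
  loadings[ne_low] <- -cfg$ne_loading

  baseline <- stats::rnorm(length(genes), mean = 6, sd = 1.5)
  expr <- baseline + outer(loadings, f) +
    matrix(stats::rnorm(length(genes) * n, sd = cfg$noise_sd),
           length(genes), n)
  dimnames(expr) <- list(genes, samples)

  # mock hallmark collection: two signal sets share the planted genes
  # but have disjoint filler members; decoys are filler-only
  k_fill <- cfg$set_size - length(cfg$signal_genes)
  pool <- sample(filler)
  take <- function(i, m) pool[seq((i - 1) * m + 1, i * m)]
  sets <- list(
    MOCK_E2F_SIGNAL = c(cfg$signal_genes, take(1, k_fill)),
    MOCK_G2M_SIGNAL = c(cfg$signal_genes, take(2, k_fill))
  )
  used <- 2 * k_fill
  for (d in seq_len(cfg$n_sets - 2)) {
    sets[[sprintf("MOCK_DECOY_%02d", d)]] <-
      pool[used + seq_len(cfg$set_size)]
    used <- used + cfg$set_size
  }

  cn <- cbind(MYC = 0.45 + 0.30 * f + stats::rnorm(n, sd = 0.15),
              MYCL = 0.10 + 0.10 * f + stats::rnorm(n, sd = 0.15),
              MYCN = 0.10 + 0.10 * f + stats::rnorm(n, sd = 0.15))
  drug_cols <- c("AZD-7762", "MK-1775",
                 sprintf("RSDRUG%02d", seq_len(cfg$n_drugs_per_class)),
                 sprintf("MAPKDRUG%02d", seq_len(cfg$n_drugs_per_class)))
  drug <- matrix(NA_real_, n, length(drug_cols),
                 dimnames = list(samples, drug_cols))
  drug[, "AZD-7762"] <- 5.8 + 1.2 * f + stats::rnorm(n, sd = 0.8)
  drug[, "MK-1775"] <- 5.5 + 1.0 * f + stats::rnorm(n, sd = 0.8)
  for (j in seq_len(cfg$n_drugs_per_class)) {
    drug[, sprintf("RSDRUG%02d", j)] <-
      cfg$drug_loading * f + stats::rnorm(n)
    drug[, sprintf("MAPKDRUG%02d", j)] <-
      -cfg$drug_loading * f + stats::rnorm(n)
  }
  rppa <- cbind(Chk1_pS345 = 0.10 + 0.15 * f + stats::rnorm(n, sd = 0.10))
  rownames(cn) <- rownames(rppa) <- samples

  list(expr = expr, cn = cn, drug = drug, rppa = rppa, sets = sets,
       ne_high_set = ne_high, ne_low_set = ne_low,
       truth = list(factor = stats::setNames(f, samples),
                    loadings = loadings,
                    signal_sets = c("MOCK_E2F_SIGNAL", "MOCK_G2M_SIGNAL"),
                    signal_genes = cfg$signal_genes,
                    negative_genes = cfg$negative_genes),
       config = cfg)
}

#' Simulate paired pre/post treatment expression
#'
#' The pre matrix is the cohort expression; post-treatment expression
#' shifts the planted signature genes along their loading sign:
#' a replication-stress inducer moves positive-loading genes up and
#' negative-loading genes down by `effect` (plus noise), a kinase
#' inhibitor does the reverse. Sample pairing is preserved.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param drug_class `"rs_inducer"` or `"kinase_inhibitor"`.
#' @param effect Shift magnitude in expression units (default 1).
#' @param seed Integer seed (required).
#' @return List with `pre` and `post` genes x samples matrices.
#' @export
simulate_treatment_dynamics <- function(cohort,
                                        drug_class = c("rs_inducer",
                                                       "kinase_inhibitor"),
                                        effect = 1, seed) {
  drug_class <- match.arg(drug_class)
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  pre <- cohort$expr
  sgn <- sign(cohort$truth$loadings)
  dir <- if (drug_class == "rs_inducer") 1 else -1
  shift <- dir * effect * sgn
  post <- pre + shift +
    matrix(stats::rnorm(length(pre), sd = 0.1), nrow(pre), ncol(pre))
  list(pre = pre, post = post)
}

#' Simulate survival times driven by the latent factor
#'
#' Exponential event times with hazard
#' `baseline_hazard * exp(beta * f)` and independent uniform censoring
#' on `(0, censor_max)`.
#'
#' @param cohort Output of [simulate_cohort()] (supplies the latent
#'   factor and the hazard defaults), or NULL when `f` is given.
#' @param f Optional per-sample factor/score vector overriding the
#'   cohort's latent factor.
#' @param beta Log hazard ratio per unit of `f`; defaults to the
#'   config's `survival_beta`. Must be supplied when `cohort` is NULL.
#' @param baseline_hazard,censor_max Override the config values.
#' @param seed Integer seed (required).
#' @return data.frame: `sample_id`, `time`, `event` (1 = event).
#' @export
simulate_survival <- function(cohort = NULL, f = NULL, beta = NULL,
                              baseline_hazard = NULL, censor_max = NULL,
                              seed) {
  if (missing(seed)) stop("seed is required")
  if (is.null(f)) f <- cohort$truth$factor
  if (is.null(beta)) beta <- cohort$config$survival_beta
  if (is.null(beta)) stop("beta unspecified")
  if (is.null(baseline_hazard))
    baseline_hazard <- if (!is.null(cohort)) cohort$config$baseline_hazard
  if (is.null(censor_max))
    censor_max <- if (!is.null(cohort)) cohort$config$censor_max
  if (is.null(baseline_hazard) || baseline_hazard <= 0)
    stop("baseline hazard must be positive")
  set.seed(as.integer(seed))
  n <- length(f)
  t_event <- stats::rexp(n, rate = baseline_hazard * exp(beta * f))
  t_cens <- stats::runif(n, 0, censor_max)
  event <- as.integer(t_event <= t_cens)
  if (all(event == 0)) stop("no events")
  data.frame(sample_id = if (!is.null(names(f))) names(f)
                         else sprintf("S%03d", seq_len(n)),
             time = pmin(t_event, t_cens), event = event,
             stringsAsFactors = FALSE, row.names = NULL)
}
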