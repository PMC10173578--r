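## Synthetic two-sample GWAS summary statistics under a known causal DAG
## (1 exposure -> k mediators -> outcome, plus a direct edge), with
## closed-form ground truth for every estimand.

.GENERATOR_VERSION <- "1.0"

#' Build a simulation design (DagSpec)
#'
#' Defaults instantiate a study-shaped network: one continuous exposure,
#' four mediators and a binary outcome with case fraction 0.1, GWAS sample
#' sizes of 100,000 per trait, 50 instruments per trait each explaining a
#' total of 5% of trait variance, and edge coefficients giving a combined
#' proportion mediated of ~65% (a = -0.50, -0.40, -0.40, -0.25;
#' b = 0.20, 0.15, 0.12, 0.08; direct c = -0.1228).
#'
#' @param n_mediators number of mediators k.
#' @param a exposure -> mediator coefficients (length k).
#' @param b mediator -> outcome coefficients, log-odds scale (length k).
#' @param c_direct direct exposure -> outcome coefficient (log-odds).
#' @param n_snps instruments per trait; scalar or length k+1
#'   (exposure first).
#' @param h2 variance explained by each trait's instruments; scalar or
#'   length k+1.
#' @param n_sample GWAS sample sizes; scalar or length k+2 (exposure,
#'   mediators, outcome).
#' @param outcome_type `"binary"` (default) or `"continuous"`.
#' @param case_fraction outcome case fraction K.
#' @param pleio_frac fraction of exposure instruments given a direct
#'   pleiotropic outcome offset.
#' @param pleio_mean,pleio_sd offset distribution (applied on the
#'   exposure-increasing allele direction, so a nonzero mean is
#'   directional pleiotropy).
#' @param tau2 extra outcome-effect variance (overdispersion).
#' @param palin_frac fraction of palindromic (A/T, C/G) SNPs generated, to
#'   exercise harmonization.
#' @param seed mandatory RNG seed.
#' @return a validated [DagSpec-class]
#' @export
dagSpec <- function(n_mediators = 4L,
                    a = c(-0.50, -0.40, -0.40, -0.25),
                    b = c(0.20, 0.15, 0.12, 0.08),
                    c_direct = -0.1228,
                    n_snps = 50L, h2 = 0.05, n_sample = 1e5,
                    outcome_type = c("binary", "continuous"),
                    case_fraction = 0.1,
                    pleio_frac = 0, pleio_mean = 0, pleio_sd = 0,
                    tau2 = 0, palin_frac = 0, seed) {
  outcome_type <- match.arg(outcome_type)
  .assert(!missing(seed), "seed is mandatory in a DagSpec")
  k <- as.integer(n_mediators)
  if (length(n_snps) == 1L) n_snps <- rep(n_snps, k + 1L)
  if (length(h2) == 1L) h2 <- rep(h2, k + 1L)
  if (length(n_sample) == 1L) n_sample <- rep(n_sample, k + 2L)
  spec <- new("DagSpec", nMediators = k, a = as.numeric(a),
              b = as.numeric(b), cDirect = c_direct,
              nSnps = as.integer(n_snps), h2 = as.numeric(h2),
              nSample = as.numeric(n_sample), outcomeType = outcome_type,
              caseFraction = case_fraction, pleioFrac = pleio_frac,
              pleioMean = pleio_mean, pleioSD = pleio_sd, tau2 = tau2,
              palinFrac = palin_frac, seed = as.integer(seed))
  validObject(spec)
  spec
}

#' Closed-form true estimands of a DagSpec
#'
#' On the linear (log-odds for a binary outcome) scale:
#' total = c + sum(a_i b_i), direct = c, indirect_i = a_i b_i,
#' PM_i = 100 a_i b_i / total, combined PM = 100 sum(a_i b_i) / total.
#'
#' @param spec a [DagSpec-class]
#' @return list with `total`, `direct`, `indirect` (per mediator),
#'   `pm` (per mediator, percent), `pm_combined` (percent), and
#'   `pm_defined` (FALSE when the total effect is exactly zero).
#' @export
trueEffects <- function(spec) {
  .assert(is(spec, "DagSpec"), "spec must be a DagSpec")
  indirect <- spec@a * spec@b
  total <- spec@cDirect + sum(indirect)
  defined <- total != 0
  list(total = total, direct = spec@cDirect,
       indirect = indirect,
       pm = if (defined) 100 * indirect / total else
         rep(NA_real_, spec@nMediators),
       pm_combined = if (defined) 100 * sum(indirect) / total else
         NA_real_,
       pm_defined = defined)
}

## Draw allele pairs; palindromic pairs (A/T, C/G) at rate palin_frac.
.draw_alleles <- function(n, palin_frac) {
  pal <- stats::runif(n) < palin_frac
  non_pal <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                   c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pal_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  idx_np <- sample.int(nrow(non_pal), n, replace = TRUE)
  idx_p <- sample.int(nrow(pal_pairs), n, replace = TRUE)
  ea <- ifelse(pal, pal_pairs[idx_p, 1], non_pal[idx_np, 1])
  oa <- ifelse(pal, pal_pairs[idx_p, 2], non_pal[idx_np, 2])
  list(ea = ea, oa = oa)
}

#' Generate a two-sample summary-statistics study under a DagSpec
#'
#' Summary statistics are generated directly on the summary scale (not via
#' individual-level genotypes): each trait's instruments get true per-SNP
#' effects sized to the trait's `h2` (random sign, allele frequencies
#' uniform on \[0.05, 0.5\]), effects propagate through the DAG (an
#' exposure SNP affects mediator i by `a_i beta`, and the outcome by
#' `(c + sum a_i b_i) beta` plus any pleiotropic offset; a mediator-i SNP
#' affects the outcome by `b_i beta`), and every GWAS table reports
#' estimated betas equal to truth plus independent noise at the
#' theoretical standard error for its sample size and allele frequency
#' (`se = 1/sqrt(2 f (1-f) n)` for continuous traits and the linearized
#' logistic `se = 1/sqrt(2 f (1-f) n K (1-K))` for the binary outcome).
#' Noise draws are never shared between tables, enforcing two-sample
#' independence. Regenerating with the same spec is bit-identical.
#'
#' @param spec a [DagSpec-class]
#' @return a [SimulatedStudy-class] with tables `exposure`, `M1`...`Mk`,
#'   `outcome`
#' @export
simulateStudy <- function(spec) {
  .assert(is(spec, "DagSpec"), "spec must be a DagSpec")
  k <- spec@nMediators
  .assert(all(spec@nSnps >= 1L),
          "every trait used as an exposure needs at least one instrument")
  m_tot <- sum(spec@nSnps)
  with_seed(spec@seed, {
    ## SNP map: owner 0 = exposure, 1..k = mediators. Positions spaced
    ## > 2 * clump window so distance-only clumping keeps all instruments.
    owner <- rep(0:k, spec@nSnps)
    snp <- sprintf("rs%06d", seq_len(m_tot))
    chr <- as.character(((seq_len(m_tot) - 1L) %% 22L) + 1L)
    pos <- 1e6 + ((seq_len(m_tot) - 1L) %/% 22L) * 2.1e7
    eaf <- stats::runif(m_tot, 0.05, 0.5)
    al <- .draw_alleles(m_tot, spec@palinFrac)
    varg <- 2 * eaf * (1 - eaf)

    ## True per-SNP effects on the owner trait, sized to h2/owner count.
    beta_own <- numeric(m_tot)
    for (t in 0:k) {
      idx <- which(owner == t)
      v <- spec@h2[t + 1L] / length(idx)
      beta_own[idx] <- sample(c(-1, 1), length(idx), replace = TRUE) *
        sqrt(v / varg[idx])
    }

    ## True effect of every SNP on every trait.
    total_path <- spec@cDirect + sum(spec@a * spec@b)
    true_exp <- ifelse(owner == 0, beta_own, 0)
    true_med <- matrix(0, m_tot, k)
    for (i in seq_len(k))
      true_med[, i] <- ifelse(owner == 0, spec@a[i] * beta_own,
                              ifelse(owner == i, beta_own, 0))
    true_out <- ifelse(owner == 0, total_path * beta_own, 0)
    for (i in seq_len(k))
      true_out <- true_out + ifelse(owner == i, spec@b[i] * beta_own, 0)

    ## Pleiotropy: direct outcome offsets for a fraction of exposure
    ## instruments, applied on the exposure-increasing allele direction so
    ## a nonzero mean offset is directional.
    exp_idx <- which(owner == 0)
    n_pleio <- round(spec@pleioFrac * length(exp_idx))
    if (n_pleio > 0) {
      chosen <- exp_idx[sample.int(length(exp_idx), n_pleio)]
      offset <- stats::rnorm(n_pleio, spec@pleioMean, spec@pleioSD)
      true_out[chosen] <- true_out[chosen] +
        sign(beta_own[chosen]) * offset
    }
    if (spec@tau2 > 0)
      true_out <- true_out + stats::rnorm(m_tot, 0, sqrt(spec@tau2))

    n_out <- spec@nSample[k + 2L]
    K <- spec@caseFraction
    se_for <- function(n, binary = FALSE)
      1 / sqrt(varg * n * if (binary) K * (1 - K) else 1)
    make_table <- function(true_beta, n, id, type, binary) {
      se <- se_for(n, binary)
      beta_hat <- true_beta + stats::rnorm(m_tot) * se
      df <- data.frame(snp = snp, chr = chr, pos = pos,
                       ea = al$ea, oa = al$oa, eaf = eaf,
                       beta = beta_hat, se = se,
                       pval = .pval_z(beta_hat / se), n = n,
                       stringsAsFactors = FALSE)
      if (binary) {
        df$ncase <- round(n * K); df$ncontrol <- n - round(n * K)
        summaryStats(df, id, "binary", n = n, ncase = round(n * K),
                     ncontrol = n - round(n * K))
      } else summaryStats(df, id, "continuous", n = n)
    }

    tables <- list(exposure = make_table(true_exp, spec@nSample[1L],
                                         "exposure", "continuous", FALSE))
    for (i in seq_len(k))
      tables[[paste0("M", i)]] <-
        make_table(true_med[, i], spec@nSample[i + 1L], paste0("M", i),
                   "continuous", FALSE)
    tables$outcome <- make_table(true_out, n_out, "outcome",
                                 spec@outcomeType,
                                 spec@outcomeType == "binary")
    new("SimulatedStudy", tables = tables, truth = trueEffects(spec),
        spec = spec, version = .GENERATOR_VERSION)
  })
}

#' Write a simulated study to disk
#'
#' One summary-statistics TSV per trait (readable by [readSumstats()]),
#' the spec as YAML, and the ground truth as JSON.
#'
#' @param study a [SimulatedStudy-class]
#' @param dir output directory (created if needed)
#' @return named character vector of the written paths, invisibly
#' @export
writeStudy <- function(study, dir) {
  .assert(is(study, "SimulatedStudy"), "study must be a SimulatedStudy")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(study@tables)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    writeSumstats(study@tables[[nm]], p)
    paths[nm] <- p
  }
  spec <- study@spec
  yaml::write_yaml(list(
    n_mediators = spec@nMediators, a = spec@a, b = spec@b,
    c_direct = spec@cDirect, n_snps = spec@nSnps, h2 = spec@h2,
    n_sample = spec@nSample, outcome_type = spec@outcomeType,
    case_fraction = spec@caseFraction, pleio_frac = spec@pleioFrac,
    pleio_mean = spec@pleioMean, pleio_sd = spec@pleioSD,
    tau2 = spec@tau2, palin_frac = spec@palinFrac, seed = spec@seed,
    generator_version = study@version),
    file.path(dir, "dag_spec.yaml"))
  paths["spec"] <- file.path(dir, "dag_spec.yaml")
  jsonlite::write_json(study@truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  paths["truth"] <- file.path(dir, "truth.json")
  invisible(paths)
}
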