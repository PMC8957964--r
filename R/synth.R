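#' Simulate epithelial/adipose reference methylomes
#'
#' Constructs two per-probe reference beta-value profiles (mammary
#' epithelium and adipose tissue) for use in two-component deconvolution.
#' Exactly `n_discriminating` probes are built with an absolute beta
#' difference of at least `delta` between the two tissues (the direction of
#' the difference is randomized per probe); all remaining probes have
#' `|beta_adipose - beta_epithelial| < delta`. With `delta = 1` the
#' discriminating probes are forced to complementary 0/1 values.
#'
#' @param n_probes Total number of probes.
#' @param n_discriminating Number of probes with `|delta beta| >= delta`.
#' @param delta Minimum absolute beta difference for discriminating probes,
#'   in (0, 1].
#' @param seed Integer RNG seed.
#' @return An object of class `reference_profiles`: a list with
#'   `probe_ids`, `beta_epithelial`, `beta_adipose` (all aligned), and a
#'   `discriminating` logical vector recording the construction.
#' @examples
#' refs <- simulate_reference_profiles(100, 10, delta = 0.8, seed = 1)
#' sum(abs(refs$beta_adipose - refs$beta_epithelial) >= 0.8)
#' @export
simulate_reference_profiles <- function(n_probes, n_discriminating,
                                        delta = 0.8, seed = 1) {
  stopifnot(n_probes >= 1, n_discriminating >= 0,
            n_discriminating <= n_probes)
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta > 1)
    stop("`delta` must be in (0, 1]", call. = FALSE)
  set.seed(as.integer(seed))
  probe_ids <- sprintf("cg%08d", seq_len(n_probes))
  disc <- rep(FALSE, n_probes)
  disc[sample.int(n_probes, n_discriminating)] <- TRUE

  epi <- adi <- numeric(n_probes)
  nd <- sum(disc)
  if (nd > 0) {
    # low end in [0, 1 - delta], gap in [delta, 1 - low]; random orientation
    low <- stats::runif(nd, 0, 1 - delta)
    gap <- delta + stats::runif(nd) * (1 - low - delta)
    flip <- stats::runif(nd) < 0.5
    epi[disc] <- ifelse(flip, low + gap, low)
    adi[disc] <- ifelse(flip, low, low + gap)
  }
  nn <- sum(!disc)
  if (nn > 0) {
    e <- stats::runif(nn)
    d <- stats::runif(nn, -1, 1) * delta * 0.999
    a <- pmin(pmax(e + d, 0), 1) # clipping only shrinks |a - e|
    epi[!disc] <- e
    adi[!disc] <- a
  }
  structure(list(probe_ids = probe_ids, beta_epithelial = epi,
                 beta_adipose = adi, discriminating = disc),
            class = "reference_profiles")
}

#' @export
print.reference_profiles <- function(x, ...) {
  cat(sprintf("Reference methylomes: %d probes (%d discriminating by construction)\n",
              length(x$probe_ids), sum(x$discriminating)))
  invisible(x)
}

#' Synthetic cohort configuration
#'
#' Bundles and validates the parameters of the cohort simulator. Defaults
#' emulate a breast-tissue methylation training cohort: 221 samples, BMI
#' log-normally distributed with median 28.24 kg/m^2 truncated to (6, 54),
#' 42 BMI-associated CpGs among 5000 probes, and two acquisition batches.
#'
#' @param n_samples Number of samples.
#' @param n_probes Number of CpG probes.
#' @param n_causal Number of probes whose methylation tracks transformed
#'   BMI.
#' @param effect_scale Beta-units of methylation shift per unit of
#'   transformed BMI at causal probes.
#' @param noise_sd Gaussian measurement noise sd, beta units.
#' @param bmi_range Length-2 truncation bounds for BMI, kg/m^2.
#' @param bmi_median Median of the (untruncated) log-normal BMI draw.
#' @param bmi_sdlog Log-scale sd of the BMI draw.
#' @param adipose_coupling Correlation in \[0, 1\] between BMI (via its
#'   normal scores) and the latent adipose fraction.
#' @param missing_rate Fraction of entries masked as missing, in \[0, 1).
#' @param n_batches Number of batches.
#' @param batch_shift_sd sd of additive per-probe, per-batch mean shifts,
#'   beta units.
#' @param seed Integer RNG seed.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_samples = 221, n_probes = 5000, n_causal = 42,
                         effect_scale = 0.15, noise_sd = 0.05,
                         bmi_range = c(6, 54), bmi_median = 28.24,
                         bmi_sdlog = 0.25, adipose_coupling = 0.7,
                         missing_rate = 0.02, n_batches = 2,
                         batch_shift_sd = 0.02, seed = 1) {
  stopifnot(n_samples >= 2, n_probes >= 1, n_causal >= 0,
            n_causal <= n_probes, noise_sd >= 0,
            length(bmi_range) == 2, bmi_range[1] > 0,
            bmi_range[2] > bmi_range[1],
            adipose_coupling >= 0, adipose_coupling <= 1,
            missing_rate >= 0, missing_rate < 1,
            n_batches >= 1, batch_shift_sd >= 0)
  structure(list(n_samples = as.integer(n_samples),
                 n_probes = as.integer(n_probes),
                 n_causal = as.integer(n_causal),
                 effect_scale = effect_scale, noise_sd = noise_sd,
                 bmi_range = bmi_range, bmi_median = bmi_median,
                 bmi_sdlog = bmi_sdlog,
                 adipose_coupling = adipose_coupling,
                 missing_rate = missing_rate,
                 n_batches = as.integer(n_batches),
                 batch_shift_sd = batch_shift_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# truncated log-normal draw by inverse CDF
.rlnorm_trunc <- function(n, meanlog, sdlog, lower, upper) {
  plo <- stats::plnorm(lower, meanlog, sdlog)
  phi <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, plo, phi), meanlog, sdlog)
}

# 450K-flavoured category proportions for the synthetic probe annotation
.ann_defaults <- list(
  chr_levels = as.character(1:22),
  chr_weights = c(9.7, 7.2, 5.8, 4.9, 5.0, 7.3, 5.9, 4.5, 4.1, 5.0, 5.9,
                  5.1, 2.4, 3.1, 3.1, 4.5, 5.7, 1.3, 5.3, 2.2, 1.3, 1.8),
  region_levels = c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body",
                    "3'UTR", "IGR"),
  region_weights = c(0.10, 0.14, 0.12, 0.04, 0.31, 0.04, 0.25),
  cgi_levels = c("island", "shore", "shelf", "open_sea"),
  cgi_weights = c(0.31, 0.23, 0.10, 0.36),
  snp_rate = 0.02
)

#' Simulate a methylation cohort with known ground truth
#'
#' Generates a breast-tissue-like cohort: each sample's methylome is a
#' two-component mixture `f * beta_adipose + (1 - f) * beta_epithelial`
#' with per-sample adipose fraction `f` correlated with BMI; a set of
#' causal probes additionally shifts by `effect_scale * F(BMI)` on the
#' beta scale (F the piecewise trait transform); additive per-batch mean
#' shifts and Gaussian noise are applied with clipping to \[0, 1\], then a
#' missing-value mask. Causal probes are assigned identical values in both
#' reference profiles so that their BMI signal is orthogonal to tissue
#' composition; at `noise_sd = 0` regressing a causal probe's beta on
#' F(BMI) recovers `effect_scale` exactly.
#'
#' Alongside methylation the simulator emits: a probe annotation table
#' with 450K-style categories; an expression matrix in which genes of
#' promoter probes (TSS200/TSS1500) decrease with their probe's beta while
#' other genes are independent, and the built-in immune-signature genes
#' are appended with expression mildly increasing in transformed BMI;
#' per-sample non-synonymous mutation counts
#' (Poisson, rate mildly increasing with transformed BMI); and a clinical
#' table.
#'
#' @param config A [synth_config()] object.
#' @param refs A `reference_profiles` object covering `config$n_probes`
#'   probes (see [simulate_reference_profiles()]).
#' @return An object of class `synthetic_cohort`: list with `beta`
#'   (probes x samples matrix, `NA` = missing), `annotation` (data frame),
#'   `true_bmi`, `true_adipose_fraction`, `causal_probes`, `batch_labels`,
#'   `expression` (genes x samples), `mutation_counts`, `clinical`,
#'   `refs_used` (references after the causal-probe override), and
#'   `config`.
#' @examples
#' cfg <- synth_config(n_samples = 40, n_probes = 200, n_causal = 5,
#'                     missing_rate = 0, seed = 3)
#' refs <- simulate_reference_profiles(200, 20, delta = 0.8, seed = 3)
#' coh <- simulate_cohort(cfg, refs)
#' range(coh$beta, na.rm = TRUE)
#' @export
simulate_cohort <- function(config, refs) {
  stopifnot(inherits(config, "synth_config"),
            inherits(refs, "reference_profiles"))
  p <- config$n_probes
  n <- config$n_samples
  if (length(refs$probe_ids) != p)
    stop(sprintf("reference profiles cover %d probes but config requires %d",
                 length(refs$probe_ids), p), call. = FALSE)
  set.seed(config$seed)

  probe_ids <- refs$probe_ids
  sample_ids <- sprintf("S%04d", seq_len(n))

  ## BMI and latent adipose fraction
  bmi <- .rlnorm_trunc(n, log(config$bmi_median), config$bmi_sdlog,
                       config$bmi_range[1], config$bmi_range[2])
  z_bmi <- stats::qnorm((rank(bmi, ties.method = "first") - 0.5) / n)
  rho <- config$adipose_coupling
  z_f <- rho * z_bmi + sqrt(1 - rho^2) * stats::rnorm(n)
  frac <- stats::pnorm(z_f)

  ## annotation
  ad <- .ann_defaults
  ann <- data.frame(
    probe_id = probe_ids,
    chr = sample(ad$chr_levels, p, replace = TRUE, prob = ad$chr_weights),
    pos = sample.int(2e8, p, replace = TRUE),
    gene = "",
    region_group = sample(ad$region_levels, p, replace = TRUE,
                          prob = ad$region_weights),
    cgi_relation = sample(ad$cgi_levels, p, replace = TRUE,
                          prob = ad$cgi_weights),
    snp_flag = stats::runif(p) < ad$snp_rate,
    stringsAsFactors = FALSE)
  genic <- ann$region_group != "IGR"
  ann$gene[genic] <- sprintf("GENE%05d", seq_len(sum(genic)))

  ## causal probes: sampled among non-SNP probes; references overridden to
  ## a shared mid-range value so composition and BMI signals decouple
  eligible <- which(!ann$snp_flag)
  if (length(eligible) < config$n_causal)
    stop("not enough SNP-free probes for the requested causal set",
         call. = FALSE)
  causal_idx <- sort(sample(eligible, config$n_causal))
  epi <- refs$beta_epithelial
  adi <- refs$beta_adipose
  if (config$n_causal > 0) {
    base_causal <- stats::runif(config$n_causal, 0.3, 0.6)
    epi[causal_idx] <- base_causal
    adi[causal_idx] <- base_causal
  }

  ## mixture + causal shift + batch shift, clip; noise, clip
  beta <- epi %o% (1 - frac) + adi %o% frac
  fb <- f_bmi(bmi)
  if (config$n_causal > 0)
    beta[causal_idx, ] <- beta[causal_idx, ] +
      matrix(config$effect_scale * fb, nrow = config$n_causal,
             ncol = n, byrow = TRUE)
  batch <- sample(rep_len(seq_len(config$n_batches), n))
  if (config$n_batches > 1 && config$batch_shift_sd > 0) {
    shifts <- matrix(stats::rnorm(p * config$n_batches, 0,
                                  config$batch_shift_sd),
                     nrow = p)
    beta <- beta + shifts[, batch]
  }
  beta <- pmin(pmax(beta, 0), 1)
  if (config$noise_sd > 0)
    beta <- pmin(pmax(beta + stats::rnorm(p * n, 0, config$noise_sd), 0), 1)

  ## missing mask; keep every probe and sample with >= 1 observation
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(p * n) < config$missing_rate, nrow = p)
    all_miss_probe <- which(rowSums(!mask) == 0)
    for (i in all_miss_probe) mask[i, sample.int(n, 1)] <- FALSE
    all_miss_sample <- which(colSums(!mask) == 0)
    for (j in all_miss_sample) mask[sample.int(p, 1), j] <- FALSE
    beta[mask] <- NA_real_
  }
  dimnames(beta) <- list(probe_ids, sample_ids)

  ## expression: promoter genes negatively coupled to their probe's beta
  promoter <- genic & ann$region_group %in% c("TSS200", "TSS1500")
  genes <- ann$gene[genic]
  expr <- matrix(stats::rnorm(sum(genic) * n, mean = 8, sd = 1.5),
                 nrow = sum(genic), dimnames = list(genes, sample_ids))
  if (any(promoter)) {
    pb <- beta[promoter, , drop = FALSE]
    pb[is.na(pb)] <- 0.5
    expr[match(ann$gene[promoter], genes), ] <-
      10 - 5 * pb + matrix(stats::rnorm(sum(promoter) * n, 0, 1),
                           nrow = sum(promoter))
  }

  ## immune-response marker genes (built-in signatures), expression
  ## mildly increasing with transformed BMI
  imm_genes <- unique(unlist(lapply(builtin_signatures(), `[[`, "genes")))
  imm <- 8 + matrix(0.8 * as.numeric(scale(fb)),
                    nrow = length(imm_genes), ncol = n, byrow = TRUE) +
    matrix(stats::rnorm(length(imm_genes) * n), nrow = length(imm_genes))
  dimnames(imm) <- list(imm_genes, sample_ids)
  expr <- rbind(expr, imm)

  ## non-synonymous mutation counts, rate mildly increasing with F(BMI)
  mu <- exp(log(40) + 0.4 * as.numeric(scale(fb)))
  mut <- stats::rpois(n, mu)

  clinical <- data.frame(
    sample_id = sample_ids,
    bmi = bmi,
    batch = batch,
    age = round(pmin(pmax(stats::rnorm(n, 50, 12), 18), 90)),
    stringsAsFactors = FALSE)
  clinical$menopause <- ifelse(clinical$age >= 51, "post", "pre")

  names(bmi) <- names(frac) <- sample_ids
  names(batch) <- names(mut) <- sample_ids
  refs_used <- structure(list(probe_ids = probe_ids, beta_epithelial = epi,
                              beta_adipose = adi,
                              discriminating = refs$discriminating),
                         class = "reference_profiles")
  structure(list(beta = beta, annotation = ann, true_bmi = bmi,
                 true_adipose_fraction = frac,
                 causal_probes = probe_ids[causal_idx],
                 batch_labels = batch, expression = expr,
                 mutation_counts = mut, clinical = clinical,
                 refs_used = refs_used, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("Synthetic methylation cohort: %d probes x %d samples\n",
                     "  causal probes: %d; batches: %d; missing: %.1f%%\n",
                     "  BMI range: %.1f-%.1f kg/m^2\n"),
              nrow(x$beta), ncol(x$beta), length(x$causal_probes),
              x$config$n_batches, 100 * mean(is.na(x$beta)),
              min(x$true_bmi), max(x$true_bmi)))
  invisible(x)
}
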