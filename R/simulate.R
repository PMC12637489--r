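#' Simulation configuration for a synthetic 4-plex TMT proximity experiment
#'
#' Defines the generative model for a TurboID/TMT experiment with four
#' channels: a no-ligase control, a nuclear spatial control, and two
#' independent bait replicates. Proteins fall into six classes: the bait
#' itself, true bait-proximal proteins, generic nuclear background,
#' ER-membrane false positives, cell-membrane false positives, and
#' endogenous-biotin/bead contaminants.
#'
#' Per protein and channel, log2 intensity =
#' per-protein abundance + class/channel effect + Gaussian noise, then
#' exponentiated, so reporter intensities are log-normal. Channel effects:
#' the no-ligase channel carries only the contaminant elevation (contaminants
#' are elevated in every channel, including no-ligase, which is exactly what
#' the first filter removes); the spatial-control channel adds the generic
#' labeling effect to every nuclear class (background, both false-positive
#' classes, true proximal, bait); the bait channels add the generic labeling
#' effect to those classes plus `bait_effect` to true-proximal proteins and
#' `bait_self_effect` to the bait (self-biotinylation is the strongest
#' signal). The Gaussian noise of the two bait channels is correlated
#' `replicate_rho` within protein; all other channels have independent noise.
#'
#' @param n_background Number of generic nuclear-background proteins.
#' @param n_true_proximal Number of true bait-proximal proteins.
#' @param n_er_fp Number of ER-membrane false-positive proteins.
#' @param n_cm_fp Number of cell-membrane false-positive proteins.
#' @param n_contaminant Number of endogenous-biotin/bead contaminants.
#' @param bait_effect Mean log2 enrichment of true-proximal proteins over the
#'   spatial control.
#' @param bait_vs_noligase_effect Mean log2 enrichment of any ligase-labeled
#'   protein over the no-ligase control (streptavidin capture of biotinylated
#'   vs unlabeled material).
#' @param bait_self_effect Mean log2 enrichment of the bait itself over the
#'   spatial control; defaults to `2 * bait_effect` so bait self-labeling is
#'   the largest effect in the experiment.
#' @param contaminant_effect Log2 elevation of contaminants in every channel.
#' @param noise_sd Per-channel log2-intensity noise standard deviation.
#' @param replicate_rho Correlation of the two bait channels' per-protein
#'   noise, in `[-1, 1]`; models shared biology between the two independent
#'   pulldowns within one plex.
#' @param base_log_intensity Location (log2 scale) of the log-normal
#'   reporter-intensity distribution.
#' @param abundance_sd Between-protein spread (log2) of baseline abundance;
#'   cancels in all ratios.
#' @param peptide_lambda Mean unique-peptide count; counts are drawn as
#'   `1 + Poisson(peptide_lambda - 1)`, guaranteeing at least one peptide.
#' @param seed Integer RNG seed; a fixed seed gives bit-identical output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_background = 2000,
                       n_true_proximal = 25,
                       n_er_fp = 150,
                       n_cm_fp = 150,
                       n_contaminant = 100,
                       bait_effect = 2.0,
                       bait_vs_noligase_effect = 2.0,
                       bait_self_effect = 2 * bait_effect,
                       contaminant_effect = 3.0,
                       noise_sd = 0.5,
                       replicate_rho = 0.9,
                       base_log_intensity = 16,
                       abundance_sd = 2.0,
                       peptide_lambda = 6,
                       seed = 7L) {
  cfg <- list(n_background = n_background, n_true_proximal = n_true_proximal,
              n_er_fp = n_er_fp, n_cm_fp = n_cm_fp,
              n_contaminant = n_contaminant, bait_effect = bait_effect,
              bait_vs_noligase_effect = bait_vs_noligase_effect,
              bait_self_effect = bait_self_effect,
              contaminant_effect = contaminant_effect, noise_sd = noise_sd,
              replicate_rho = replicate_rho,
              base_log_intensity = base_log_intensity,
              abundance_sd = abundance_sd, peptide_lambda = peptide_lambda,
              seed = as.integer(seed))
  counts <- unlist(cfg[c("n_background", "n_true_proximal", "n_er_fp",
                         "n_cm_fp", "n_contaminant")])
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("simulation counts must be non-negative integers", call. = FALSE)
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (abs(cfg$replicate_rho) > 1) {
    stop("replicate_rho must lie in [-1, 1]", call. = FALSE)
  }
  if (cfg$peptide_lambda < 1) stop("peptide_lambda must be >= 1", call. = FALSE)
  if (cfg$abundance_sd < 0) stop("abundance_sd must be >= 0", call. = FALSE)
  structure(cfg, class = "sim_config")
}

.sim_classes <- c("bait", "true_proximal", "background", "er_fp", "cm_fp",
                  "contaminant")

sim_class_vector <- function(config) {
  rep(.sim_classes,
      times = c(1L, config$n_true_proximal, config$n_background,
                config$n_er_fp, config$n_cm_fp, config$n_contaminant))
}

# mean log2 channel effect for one class in one role
class_channel_effect <- function(config, class, role) {
  labeled <- class %in% c("bait", "true_proximal", "background", "er_fp", "cm_fp")
  eff <- numeric(length(class))
  if (role == "no_ligase") {
    eff[class == "contaminant"] <- config$contaminant_effect
  } else if (role == "spatial_control") {
    eff[labeled] <- config$bait_vs_noligase_effect
    eff[class == "contaminant"] <- config$contaminant_effect
  } else if (role %in% c("bait_rep1", "bait_rep2")) {
    eff[labeled] <- config$bait_vs_noligase_effect
    eff[class == "true_proximal"] <- config$bait_vs_noligase_effect + config$bait_effect
    eff[class == "bait"] <- config$bait_vs_noligase_effect + config$bait_self_effect
    eff[class == "contaminant"] <- config$contaminant_effect
  } else {
    stop("unknown channel role: ", role, call. = FALSE)
  }
  eff
}

#' Generate a synthetic 4-plex TMT proximity-labeling experiment
#'
#' Draws one experiment from the generative model described in
#' [sim_config()]. The draw order is fixed (per-protein abundance; no-ligase
#' noise; spatial-control noise; correlated bait-replicate noise; peptide
#' counts), so a fixed seed yields bit-identical output.
#'
#' @param config A `sim_config`.
#' @return A list with elements:
#' \describe{
#'   \item{quant}{a `quant_table` of reporter intensities (channels
#'     `134N`, `133C`, `133N`, `126C` in the default role mapping);}
#'   \item{truth}{data.frame `accession`, `class` — the ground-truth class
#'     labels, one `bait` row, classes partitioning all accessions;}
#'   \item{er_list, cm_list}{`compartment_list`s holding exactly the
#'     simulated ER-membrane and cell-membrane false-positive accessions;}
#'   \item{bait}{the bait accession;}
#'   \item{config}{the input configuration.}
#' }
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  roles <- default_channel_roles()
  classes <- sim_class_vector(config)
  n <- length(classes)
  prefix <- c(bait = "BAIT", true_proximal = "TP", background = "BG",
              er_fp = "ER", cm_fp = "CM", contaminant = "CT")
  idx <- stats::ave(seq_len(n), classes, FUN = seq_along)
  accession <- ifelse(classes == "bait", "BAIT00001",
                      sprintf("%s%05d", prefix[classes], idx))
  set.seed(config$seed)
  abundance <- stats::rnorm(n, config$base_log_intensity, config$abundance_sd)
  eps_nl <- stats::rnorm(n, 0, config$noise_sd)
  eps_sp <- stats::rnorm(n, 0, config$noise_sd)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  rho <- config$replicate_rho
  eta1 <- config$noise_sd * z1
  eta2 <- config$noise_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
  peptides <- 1L + stats::rpois(n, config$peptide_lambda - 1)

  log2_int <- cbind(
    abundance + class_channel_effect(config, classes, "no_ligase") + eps_nl,
    abundance + class_channel_effect(config, classes, "spatial_control") + eps_sp,
    abundance + class_channel_effect(config, classes, "bait_rep1") + eta1,
    abundance + class_channel_effect(config, classes, "bait_rep2") + eta2)
  colnames(log2_int) <- unname(roles[c("no_ligase", "spatial_control",
                                       "bait_rep1", "bait_rep2")])

  quant <- data.frame(accession = accession,
                      gene_symbol = accession,
                      unique_peptides = peptides,
                      stringsAsFactors = FALSE)
  for (ch in colnames(log2_int)) quant[[ch]] <- 2^log2_int[, ch]
  quant <- as_quant_table(quant, channels = colnames(log2_int),
                          channel_roles = roles)

  er_acc <- accession[classes == "er_fp"]
  cm_acc <- accession[classes == "cm_fp"]
  list(quant = quant,
       truth = data.frame(accession = accession, class = classes,
                          stringsAsFactors = FALSE),
       er_list = if (length(er_acc)) compartment_list("ER_membrane", er_acc) else NULL,
       cm_list = if (length(cm_acc)) compartment_list("cell_membrane", cm_acc) else NULL,
       bait = "BAIT00001",
       config = config)
}

#' Noise-free expected log2 ratio implied by the generative model
#'
#' Closed-form mean log2 ratio for one protein class on one filter axis,
#' used by recovery tests to check that simulated data converge to the
#' model's means.
#'
#' @param config A `sim_config`.
#' @param class One of `bait`, `true_proximal`, `background`, `er_fp`,
#'   `cm_fp`, `contaminant`.
#' @param axis `"vs_no_ligase"` (bait replicate over no-ligase control) or
#'   `"vs_spatial_control"` (bait replicate over nuclear spatial control).
#' @return The expected log2 ratio (a single number).
#' @export
expected_ratio <- function(config, class, axis) {
  stopifnot(inherits(config, "sim_config"))
  if (!class %in% .sim_classes) stop("unknown class: ", class, call. = FALSE)
  if (!axis %in% c("vs_no_ligase", "vs_spatial_control")) {
    stop("unknown axis: ", axis, call. = FALSE)
  }
  num <- class_channel_effect(config, class, "bait_rep1")
  den <- if (axis == "vs_no_ligase") {
    class_channel_effect(config, class, "no_ligase")
  } else {
    class_channel_effect(config, class, "spatial_control")
  }
  num - den
}

#' Simulate GO term-name annotations for a synthetic experiment
#'
#' Assigns each protein a few term names drawn from a small vocabulary in
#' which some names carry the keywords used by the reporting categories
#' (e.g. "protein dephosphorylation", "mitochondrion organization"). Purely
#' illustrative: synthetic class labels have no biological GO structure, so
#' terms are assigned at random.
#'
#' @param accessions Character vector of protein accessions.
#' @param seed Integer RNG seed.
#' @param terms_per_protein Mean number of terms per protein (Poisson).
#' @return A `go_map` (named list of lower-cased term names).
#' @export
simulate_go_annotations <- function(accessions, seed = 1L,
                                    terms_per_protein = 2) {
  vocab <- c("protein dephosphorylation", "proteasome-mediated catabolism",
             "ubiquitin-dependent process", "protein folding",
             "protein import into nucleus", "mitochondrion organization",
             "cell division", "mitotic spindle organization",
             "rna binding", "chromatin organization", "dna repair",
             "transcription regulation", "signal transduction",
             "cytoskeleton organization", "membrane trafficking")
  set.seed(as.integer(seed))
  k <- stats::rpois(length(accessions), terms_per_protein)
  out <- lapply(k, function(m) if (m == 0) character(0) else sample(vocab, min(m, length(vocab))))
  names(out) <- accessions
  structure(out, class = "go_map")
}
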