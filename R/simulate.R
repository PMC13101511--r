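# Run expr with a local RNG stream seeded by `seed`, restoring the caller's
# .Random.seed afterwards so simulation never perturbs user RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  force(expr)
}

#' Sampling design for a simulated degradation experiment
#'
#' Defaults mirror a typical 15-day triplicate shake-flask study: sampling
#' on days 0, 1, 3, 5, 7, 9, 11, 13, 15 with three replicate flasks per
#' time point, additive measurement noise of 1 mg/L on the parent channel
#' and 0.5 mg/L on the intermediate channel, and an intermediate limit of
#' detection of 0.02 mg/L (20 ug/L, a typical UPLC LOD for aromatic acids).
#'
#' @param sample_times Sampling times, days.
#' @param n_replicates Replicate flasks per time point (>= 1).
#' @param noise_sigma_parent,noise_sigma_intermediate Additive Gaussian
#'   noise SD per channel, mg/L (>= 0).
#' @param lod_parent,lod_intermediate Limits of detection, mg/L.
#' @param noise_model \code{"gaussian"} (additive, truncated at 0; matches
#'   the parametric-bootstrap noise law) or \code{"lognormal"}
#'   (multiplicative, for robustness experiments; sigma interpreted on the
#'   log scale relative to the mean concentration).
#' @param seed Integer seed.
#' @return A \code{design_spec} list.
#' @export
design_spec <- function(sample_times = c(0, 1, 3, 5, 7, 9, 11, 13, 15),
                        n_replicates = 3,
                        noise_sigma_parent = 1,
                        noise_sigma_intermediate = 0.5,
                        lod_parent = 0,
                        lod_intermediate = 0.02,
                        noise_model = c("gaussian", "lognormal"),
                        seed = 1) {
  noise_model <- match.arg(noise_model)
  .check_times(sample_times)
  if (n_replicates < 1) stop("design_spec: n_replicates must be >= 1")
  sig <- c(noise_sigma_parent, noise_sigma_intermediate)
  if (any(!is.finite(sig)) || any(sig < 0)) {
    stop("design_spec: noise sigmas must be finite and >= 0")
  }
  structure(list(
    sample_times = sort(unique(sample_times)),
    n_replicates = as.integer(n_replicates),
    noise_sigma_parent = noise_sigma_parent,
    noise_sigma_intermediate = noise_sigma_intermediate,
    lod_parent = lod_parent,
    lod_intermediate = lod_intermediate,
    noise_model = noise_model,
    seed = as.integer(seed)
  ), class = "design_spec")
}

#' Simulate a parent/intermediate degradation time course
#'
#' Evaluates the closed-form branched-model trajectory at the design's
#' sampling times and adds per-replicate measurement noise (additive
#' Gaussian truncated at 0 by default). Observations falling below the
#' channel's limit of detection are flagged \code{below_lod} (their
#' numeric value is retained so censoring policies can be studied).
#' Fully reproducible given the design seed.
#'
#' @param params A \code{\link{kinetic_params}} truth.
#' @param design A \code{\link{design_spec}}.
#' @return A \code{\link{time_course_data}} object.
#' @examples
#' p <- kinetic_params(0.142, 0.4437, 0.150, 60)
#' d <- simulate_timecourse(p, design_spec(seed = 42))
#' head(d)
#' @export
simulate_timecourse <- function(params, design = design_spec()) {
  params <- .as_params(params)
  if (!inherits(design, "design_spec")) {
    stop("simulate_timecourse: expected a 'design_spec'")
  }
  traj <- closed_form_solution(params, design$sample_times)
  grid <- expand.grid(replicate = paste0("R", seq_len(design$n_replicates)),
                      time = design$sample_times,
                      compound = c("parent", "intermediate"),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$compound, grid$time, grid$replicate), ]
  mu <- ifelse(grid$compound == "parent",
               traj$S[match(grid$time, traj$time)],
               traj$P[match(grid$time, traj$time)])
  sig <- ifelse(grid$compound == "parent",
                design$noise_sigma_parent, design$noise_sigma_intermediate)
  conc <- .with_seed(design$seed, {
    if (design$noise_model == "gaussian") {
      pmax(0, stats::rnorm(nrow(grid), mean = mu, sd = sig))
    } else {
      ifelse(mu > 0,
             mu * exp(stats::rnorm(nrow(grid), 0, sig / pmax(mu, .Machine$double.eps))),
             0)
    }
  })
  lod <- ifelse(grid$compound == "parent",
                design$lod_parent, design$lod_intermediate)
  time_course_data(data.frame(
    time = grid$time, compound = grid$compound, replicate = grid$replicate,
    conc = conc, below_lod = conc < lod, lod = lod,
    stringsAsFactors = FALSE
  ))
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Builds a tidy Ct table in which each target gene is induced by a known
#' fold change in every treatment condition relative to a control: the
#' reference gene has a fixed baseline Ct in all strata, each target has a
#' gene-specific baseline Ct in the control, offset by \code{-log2(fold)}
#' under treatment, and Gaussian cycle noise is added to every well.
#'
#' @param true_fold_changes Named numeric vector of per-gene fold changes
#'   (> 0), applied in every treatment condition. The reference gene need
#'   not be listed (its fold is 1 by construction).
#' @param conditions Character vector of treatment condition labels.
#' @param control_condition Control condition label.
#' @param n_bio,n_tech Biological and technical replicates per stratum.
#' @param ct_noise Gaussian noise SD, cycles.
#' @param reference_gene Reference gene label.
#' @param ref_ct,target_ct Baseline Ct of the reference and the targets.
#' @param seed Integer seed.
#' @return A data.frame of Ct records for \code{\link{delta_delta_ct}}.
#' @export
simulate_ct_table <- function(true_fold_changes, conditions = "pyrene",
                              control_condition = "control",
                              n_bio = 3, n_tech = 3, ct_noise = 0.2,
                              reference_gene = "16S",
                              ref_ct = 12, target_ct = 24, seed = 1) {
  if (is.null(names(true_fold_changes)) ||
      any(!nzchar(names(true_fold_changes)))) {
    stop("simulate_ct_table: true_fold_changes must be a named vector")
  }
  if (any(!is.finite(true_fold_changes)) || any(true_fold_changes <= 0)) {
    stop("simulate_ct_table: fold changes must be finite and > 0")
  }
  genes <- setdiff(names(true_fold_changes), reference_gene)
  all_cond <- c(control_condition, conditions)
  grid <- expand.grid(gene = c(reference_gene, genes),
                      condition = all_cond,
                      bio_rep = seq_len(n_bio),
                      tech_rep = seq_len(n_tech),
                      stringsAsFactors = FALSE)
  base <- ifelse(grid$gene == reference_gene, ref_ct, target_ct)
  shift <- ifelse(grid$gene != reference_gene &
                    grid$condition != control_condition,
                  -log2(true_fold_changes[grid$gene]), 0)
  grid$ct <- .with_seed(seed,
    base + shift + stats::rnorm(nrow(grid), 0, ct_noise))
  grid[order(grid$gene, grid$condition, grid$bio_rep, grid$tech_rep), ]
}
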