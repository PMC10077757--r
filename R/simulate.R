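#' Noise model for simulated screens
#'
#' Measurement noise is additive Gaussian on the viability fraction, with
#' `replicates` independent wells per dose point. The default sigma of 0.05
#' matches a typical coefficient of variation for MTT-style viability
#' readouts.
#'
#' @param sigma Standard deviation of the additive viability noise (>= 0).
#' @param replicates Number of replicate wells per point (>= 1).
#' @return A `noise_model` list.
#' @export
noise_model <- function(sigma = 0.05, replicates = 2) {
  stopifnot(sigma >= 0, replicates >= 1)
  structure(list(sigma = sigma, replicates = replicates),
            class = "noise_model")
}

# Mean of `r` replicate draws around `mu`, one value per element of mu.
rep_mean <- function(mu, noise) {
  if (noise$sigma == 0) return(mu)
  mu + rowMeans(matrix(rnorm(length(mu) * noise$replicates, sd = noise$sigma),
                       ncol = noise$replicates))
}

# Default monotherapy grid: 6 log-spaced doses, 0.1 nM .. 10 uM.
default_dose_grid <- function() c(0.1, 1, 10, 100, 1000, 10000)

# Default combination grid: 10 five-fold steps starting at 0.03 nM.
default_combo_grid <- function() 0.03 * 5^(0:9)

# Random dose-response truths: full baseline, EC50 placed inside the grid
# so curves are identifiable, moderate Hill slopes, partial-kill plateaus.
draw_truth <- function(n, ec50_range = c(1, 1000), hill_range = c(0.8, 2.5),
                       einf_range = c(0, 0.3)) {
  tibble::tibble(
    e0 = rep(1, n),
    einf = runif(n, einf_range[1], einf_range[2]),
    ec50 = 10^runif(n, log10(ec50_range[1]), log10(ec50_range[2])),
    hill = runif(n, hill_range[1], hill_range[2])
  )
}

#' Simulate a monotherapy viability screen with known truth
#'
#' Generates raw well records for `n_lines` cell lines x `compounds` on a
#' log-spaced dose grid. True dose-response curves are four-parameter
#' logistics with randomly drawn parameters; raw signals are
#' `10000 * max(0, viability + noise)` with per-line DMSO (positive) and
#' empty-well (negative) control wells, so the output exercises the full
#' normalization path. Empty wells carry only instrument background
#' (sigma / 5), since they contain no cells.
#'
#' @param n_lines Number of cell lines.
#' @param compounds Character vector of compound names, or a count.
#' @param dose_grid Strictly increasing dose grid, nM (default the 6-point
#'   grid 0.1 nM to 10 uM).
#' @param noise A [noise_model()] (replicates become separate wells).
#' @param seed Integer seed; identical seeds give identical output.
#' @param n_controls Control wells of each role per line (default 16).
#' @return List with `wells` (raw well-record tibble, parseable by the
#'   screen schema) and `truth` (per line x compound true parameters).
#' @export
gen_monotherapy_screen <- function(n_lines = 2, compounds = 10,
                                   dose_grid = default_dose_grid(),
                                   noise = noise_model(), seed,
                                   n_controls = 16) {
  stopifnot(all(diff(dose_grid) > 0))
  if (is.numeric(compounds) && length(compounds) == 1) {
    compounds <- sprintf("CPD%03d", seq_len(compounds))
  }
  lines <- sprintf("LINE%02d", seq_len(n_lines))
  scale <- 10000
  with_seed(seed, {
    truth <- tidyr::expand_grid(cell_line = lines, compound = compounds)
    truth <- dplyr::bind_cols(truth, draw_truth(nrow(truth)))

    samp <- tidyr::expand_grid(
      truth, dose = dose_grid, replicate = seq_len(noise$replicates)
    )
    v_true <- fourpl_v(samp$dose, samp)
    samp$signal <- scale * pmax(0, v_true + rnorm(nrow(samp), sd = noise$sigma))
    samp <- samp[c("cell_line", "compound", "dose", "replicate", "signal")]
    samp$role <- "sample"

    ctrl <- tidyr::expand_grid(cell_line = lines, replicate = seq_len(n_controls),
                               role = c("pos_control", "neg_control"))
    ctrl$compound <- ifelse(ctrl$role == "pos_control", "DMSO", "empty")
    ctrl$dose <- 0
    base <- ifelse(ctrl$role == "pos_control", 1, 0)
    sdv <- ifelse(ctrl$role == "pos_control", noise$sigma, noise$sigma / 5)
    ctrl$signal <- scale * pmax(0, base + rnorm(nrow(ctrl), sd = sdv))
    wells <- dplyr::bind_rows(samp, ctrl[names(samp)])
    wells$unit <- "nM"
    wells <- wells[c("cell_line", "compound", "dose", "unit", "replicate",
                     "signal", "role")]
    list(wells = tibble::as_tibble(wells), truth = truth)
  })
}

fourpl_v <- function(dose, par) fourpl(dose, par$e0, par$einf, par$ec50, par$hill)

#' Simulate a full combination dose matrix under Bliss with planted excess
#'
#' Builds a [combination_matrix()] for one drug pair: monotherapy margins
#' follow the supplied true curves (plus noise), and each combination
#' cell's observed inhibition is
#' `clip(bliss_expected(fa, fb) + delta + noise, 0, 1)` — exact Bliss
#' independence when `delta = 0`, a uniform planted synergy excess
#' otherwise. Replicate draws are clipped per well and then averaged,
#' mirroring how replicate plates are processed.
#'
#' @param truth_a,truth_b Lists/rows with `e0`, `einf`, `ec50`, `hill` for
#'   the two drugs.
#' @param delta Planted uniform Bliss excess, `|delta| <= 0.5`.
#' @param dose_a,dose_b Dose grids, nM (default 10 five-fold steps from
#'   0.03 nM).
#' @param noise A [noise_model()] (default singlicate, sigma 0.05).
#' @param seed Integer seed.
#' @return List with `matrix` (a `combo_matrix`) and `truth`.
#' @export
gen_combination_matrix <- function(truth_a, truth_b, delta = 0,
                                   dose_a = default_combo_grid(),
                                   dose_b = default_combo_grid(),
                                   noise = noise_model(0.05, 1), seed) {
  stopifnot(abs(delta) <= 0.5)
  with_seed(seed, {
    va <- fourpl_v(dose_a, truth_a)
    vb <- fourpl_v(dose_b, truth_b)
    fa <- clip(1 - va, 0, 1)
    fb <- clip(1 - vb, 0, 1)
    expected <- outer(fa, fb, bliss_expected)
    r <- noise$replicates
    obs <- matrix(0, length(dose_a), length(dose_b))
    for (k in seq_len(r)) {
      obs <- obs + clip(expected + delta +
                          rnorm(length(expected), sd = noise$sigma), 0, 1)
    }
    obs <- obs / r
    m <- combination_matrix(
      viability = 1 - obs, dose_a = dose_a, dose_b = dose_b,
      mono_a = rep_mean(va, noise), mono_b = rep_mean(vb, noise),
      compound_a = "drugA", compound_b = "drugB"
    )
    list(matrix = m,
         truth = list(truth_a = truth_a, truth_b = truth_b, delta = delta,
                      expected_inhibition = expected))
  })
}

#' Simulate an anchored combination library screen
#'
#' Emulates a high-throughput anchored screen for one cell line: a library
#' of compounds is titrated over a 6-point dose grid alone and on top of an
#' anchor drug held at its IC15, IC25 and IC50 (anchor doses derived by
#' inverting the anchor's true curve at viabilities 0.85, 0.75 and 0.50). A
#' chosen fraction of library compounds is synergistic, receiving a uniform
#' planted Bliss excess `delta` in every combination cell; the rest combine
#' under exact Bliss independence. Combination wells are generated as in
#' [gen_combination_matrix()]; monotherapy and anchor-alone wells carry the
#' same additive noise. Screens of this design are typically run in
#' singlicate, the default here.
#'
#' @param n_compounds Library size (default 198).
#' @param frac_synergistic Fraction of compounds given the planted excess.
#' @param delta Planted Bliss excess for synergistic compounds.
#' @param anchor_truth True anchor curve (defaults to a potent inhibitor:
#'   EC50 50 nM, Hill 1.2, near-complete kill).
#' @param dose_grid Library dose grid, nM.
#' @param noise A [noise_model()] (default singlicate, sigma 0.05).
#' @param seed Integer seed.
#' @param cell_line Cell-line identifier for the generated screen.
#' @param anchor_replicates Replicate wells behind the anchor-alone margin
#'   (default 16: anchor-only reference wells appear on every plate).
#' @return List with tibbles `mono`, `combo`, `anchor_mono` (the input
#'   format of [score_anchored_screen()]) and `truth` (per-compound
#'   parameters and the planted synergy flag).
#' @export
gen_anchored_library_screen <- function(n_compounds = 198,
                                        frac_synergistic = 0, delta = 0.2,
                                        anchor_truth = list(e0 = 1, einf = 0.02,
                                                            ec50 = 50, hill = 1.2),
                                        dose_grid = default_dose_grid(),
                                        noise = noise_model(0.05, 1), seed,
                                        cell_line = "LINE01",
                                        anchor_replicates = 16) {
  stopifnot(frac_synergistic >= 0, frac_synergistic <= 1)
  anchors <- c(IC15 = 0.85, IC25 = 0.75, IC50 = 0.50)
  with_seed(seed, {
    # Invert the anchor's true curve at the target viabilities.
    ratio <- (anchor_truth$e0 - anchors) / (anchors - anchor_truth$einf)
    anchor_dose <- anchor_truth$ec50 * ratio^(1 / anchor_truth$hill)
    fa_true <- clip(1 - anchors, 0, 1)

    compounds <- sprintf("CPD%03d", seq_len(n_compounds))
    truth <- draw_truth(n_compounds, ec50_range = c(10, 5000),
                        hill_range = c(0.8, 2), einf_range = c(0, 0.9))
    truth <- dplyr::bind_cols(tibble::tibble(compound = compounds), truth)
    n_syn <- round(frac_synergistic * n_compounds)
    truth$synergistic <- seq_len(n_compounds) %in%
      sample.int(n_compounds, n_syn)
    truth$delta <- ifelse(truth$synergistic, delta, 0)

    mono <- tidyr::expand_grid(cell_line = cell_line,
                               compound = compounds, dose = dose_grid)
    par <- truth[match(mono$compound, truth$compound), ]
    mono$viability <- rep_mean(fourpl_v(mono$dose, par), noise)

    combo <- tidyr::expand_grid(
      cell_line = cell_line,
      anchor = names(anchors),
      compound = compounds,
      dose = dose_grid
    )
    combo$anchor_dose <- anchor_dose[combo$anchor]
    parc <- truth[match(combo$compound, truth$compound), ]
    fb <- clip(1 - fourpl_v(combo$dose, parc), 0, 1)
    expected <- bliss_expected(fa_true[combo$anchor], fb)
    r <- noise$replicates
    obs <- 0
    for (k in seq_len(r)) {
      obs <- obs + clip(expected + parc$delta +
                          rnorm(nrow(combo), sd = noise$sigma), 0, 1)
    }
    combo$viability <- 1 - obs / r
    combo <- combo[c("cell_line", "anchor", "anchor_dose", "compound",
                     "dose", "viability")]

    # Anchor-alone wells recur on every assay plate of an anchored screen,
    # so the anchor margin is far better replicated than any library point.
    anchor_noise <- noise_model(noise$sigma, anchor_replicates)
    anchor_mono <- tibble::tibble(
      cell_line = cell_line, anchor = names(anchors),
      anchor_dose = unname(anchor_dose),
      viability = rep_mean(unname(anchors), anchor_noise)
    )
    list(mono = mono, combo = combo, anchor_mono = anchor_mono,
         truth = truth, anchor_truth = anchor_truth)
  })
}

#' Simulate a cell-line panel sensitivity dataset
#'
#' Builds a [sensitivity_dataset()] emulating a pediatric/adult panel
#' screened against a compound library with pathway annotations. Each
#' compound has a baseline AUC; compounds in `shifted_pathways` have their
#' AUC shifted by the given amount in pediatric lines only (negative shift
#' = pediatric lines more sensitive); Gaussian noise is added and values
#' truncated to `[0, 1]`.
#'
#' @param n_ped,n_adult Numbers of pediatric and adult cell lines.
#' @param n_compounds Library size (default 198).
#' @param n_pathways Number of target pathways annotated round-robin.
#' @param shifted_pathways Named numeric vector, pathway -> AUC shift in
#'   pediatric lines (shifts in `[-0.5, 0.5]`).
#' @param noise_sd SD of the additive AUC noise (default 0.1).
#' @param seed Integer seed.
#' @param frac_mutant Fraction of lines carrying the STAG2 mutation flag.
#' @return List with `dataset` (a `sensitivity_dataset`) and `truth`.
#' @export
gen_sensitivity_dataset <- function(n_ped = 40, n_adult = 200,
                                    n_compounds = 198, n_pathways = 15,
                                    shifted_pathways = c(), noise_sd = 0.1,
                                    seed, frac_mutant = 0.1) {
  if (length(shifted_pathways) > 0) {
    stopifnot(all(abs(shifted_pathways) <= 0.5))
  }
  with_seed(seed, {
    lines <- c(sprintf("PED%03d", seq_len(n_ped)),
               sprintf("ADT%03d", seq_len(n_adult)))
    pediatric <- rep(c(TRUE, FALSE), c(n_ped, n_adult))
    ped_types <- c("ES", "MB", "NB", "OS", "RMS")
    adult_types <- sprintf("adult_%d", 1:5)
    tumor_type <- c(sample(ped_types, n_ped, replace = TRUE),
                    sample(adult_types, n_adult, replace = TRUE))
    compounds <- sprintf("CPD%03d", seq_len(n_compounds))
    pathways <- sprintf("PATHWAY_%02d", seq_len(n_pathways))
    pathway <- rep_len(pathways, n_compounds)
    target <- sprintf("TARGET_%03d", rep(seq_len(ceiling(n_compounds / 2)),
                                         each = 2)[seq_len(n_compounds)])
    base <- runif(n_compounds, 0.3, 0.9)
    shift <- rep(0, n_compounds)
    if (length(shifted_pathways) > 0) {
      s <- unname(shifted_pathways[pathway])
      shift[!is.na(s)] <- s[!is.na(s)]
    }

    auc <- outer(pediatric, shift) +
      matrix(base, length(lines), n_compounds, byrow = TRUE) +
      matrix(rnorm(length(lines) * n_compounds, sd = noise_sd),
             length(lines), n_compounds)
    auc <- clip(auc, 0, 1)
    dimnames(auc) <- list(lines, compounds)

    ds <- sensitivity_dataset(
      auc,
      cell_meta = tibble::tibble(
        cell_line = lines, pediatric = pediatric, tumor_type = tumor_type,
        STAG2 = runif(length(lines)) < frac_mutant
      ),
      compound_meta = tibble::tibble(
        compound = compounds, target = target, target_pathway = pathway
      )
    )
    list(dataset = ds,
         truth = list(base_auc = setNames(base, compounds),
                      shifted_pathways = shifted_pathways,
                      noise_sd = noise_sd))
  })
}

#' Simulate an expression matrix with planted gene-set associations
#'
#' Generates a genes x cell-lines expression matrix in which the genes of
#' each planted set track a compound's AUC: `expr = -beta * AUC + noise`,
#' so higher expression accompanies lower AUC (greater sensitivity) when
#' `beta > 0`. All remaining genes are pure noise. Planted sets must be
#' disjoint.
#'
#' @param n_genes Total number of genes.
#' @param planted_sets Named list of gene-identifier vectors (subsets of
#'   `G0001...`); may be empty.
#' @param beta Association coefficient(s): scalar or named per set.
#' @param dataset A [sensitivity_dataset()] supplying the AUC.
#' @param compound Compound whose AUC drives the planted signal.
#' @param noise_sd SD of the expression noise (default 1; `beta` is then
#'   expressed in noise-SD units).
#' @param seed Integer seed.
#' @return List with `expression` (matrix), `genesets` (the planted sets)
#'   and `truth`.
#' @export
gen_expression_dataset <- function(n_genes = 2000, planted_sets = list(),
                                   beta = 1, dataset, compound,
                                   noise_sd = 1, seed) {
  planted_genes <- unlist(planted_sets, use.names = FALSE)
  if (anyDuplicated(planted_genes)) abort("planted sets must be disjoint")
  if (!compound %in% colnames(dataset$auc)) {
    abort(paste0("compound absent from dataset: ", compound))
  }
  genes <- sprintf("G%04d", seq_len(n_genes))
  if (!all(planted_genes %in% genes)) {
    abort("planted set members must be among the generated gene identifiers")
  }
  if (is.null(names(beta)) && length(planted_sets) > 0) {
    beta <- setNames(rep_len(beta, length(planted_sets)), names(planted_sets))
  }
  auc <- dataset$auc[, compound]
  lines <- rownames(dataset$auc)[!is.na(auc)]
  with_seed(seed, {
    expr <- matrix(rnorm(n_genes * length(lines), sd = noise_sd),
                   n_genes, length(lines), dimnames = list(genes, lines))
    for (nm in names(planted_sets)) {
      g <- planted_sets[[nm]]
      expr[g, ] <- expr[g, , drop = FALSE] +
        matrix(-beta[[nm]] * auc[lines], length(g), length(lines),
               byrow = TRUE)
    }
    list(expression = expr, genesets = planted_sets,
         truth = list(beta = beta, compound = compound, noise_sd = noise_sd))
  })
}
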