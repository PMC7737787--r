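# Smart-seq2-like count simulator with planted cell-type, patient, cycle,
# EMT, CSC and CTA structure. Counts are negative-binomial (mean mu,
# dispersion theta, variance mu + mu^2/theta) thinned by independent
# Bernoulli dropout. Program genes are near-silent outside their program
# (a background log2 offset) and shifted by +delta log2 units inside it,
# which is what makes marker-based typing learnable at Smart-seq2-like
# depth. All draws use one stated RNG (Mersenne-Twister) under the config
# seed.

mito_gene_names <- function() {
  c("MT-ND1", "MT-ND2", "MT-ND3", "MT-ND4", "MT-ND4L", "MT-ND5", "MT-ND6",
    "MT-CO1", "MT-CO2", "MT-CO3", "MT-ATP6", "MT-ATP8", "MT-CYB")
}

#' Synthetic cohort configuration
#'
#' Defaults describe a CSF cohort like the one the pipeline targets:
#' CTC-dominated patient CSF with small T/monocyte/B admixture, 5
#' patients, Smart-seq2-like depth (hundreds to ~2000 detected genes per
#' cell), a small cycling subpopulation (7.2%), a partial-EMT CTC
#' subpopulation, patient-private expression programs and sparse CTA
#' expression.
#'
#' @param n_patients number of patients (default 5).
#' @param cells_per_patient cells per patient (default 200).
#' @param n_genes total genes, must cover the built-in program genes
#'   (default 2000).
#' @param composition named fractions over \code{T}, \code{B},
#'   \code{monocyte}, \code{CTC}; must sum to 1.
#' @param delta log2 effect of an active program (default 3, an 8x shift).
#' @param background_log2 log2 offset of program genes outside their
#'   program (default -10: near-silent, matching the marker specificity
#'   of sorted CSF populations).
#' @param nb_mean_baseline baseline negative-binomial mean per gene
#'   (default 2 reads).
#' @param nb_dispersion NB dispersion theta (default 0.5).
#' @param dropout_prob Bernoulli dropout probability (default 0.3).
#' @param mito_fraction_target expected mitochondrial count fraction
#'   (default 0.05).
#' @param cycling_fraction fraction of CTCs in the cycling state
#'   (default 0.072).
#' @param partial_emt_fraction fraction of CTCs with the mesenchymal/CSC
#'   program active (default 0.30).
#' @param cta_detect_prob net per-gene, per-CTC detection probability for
#'   catalogue CTA genes (default 0.02); this is the post-dropout
#'   detection rate.
#' @param csc_positive_rates named per-marker net positivity rates among
#'   CTCs for the CSC candidate markers.
#' @param n_patient_program_genes patient-private program genes per
#'   patient (default 30).
#' @param programs \code{"full"} (all built-in gene programs) or
#'   \code{"minimal"} (marker panels and mitochondrial genes only; for
#'   very small fixtures).
#' @param seed integer seed.
#' @return Validated list of class \code{SyntheticConfig}.
#' @export
synthetic_config <- function(n_patients = 5, cells_per_patient = 200,
                             n_genes = 2000,
                             composition = c(T = 0.10, B = 0.02,
                                             monocyte = 0.08, CTC = 0.80),
                             delta = 3, background_log2 = -10,
                             nb_mean_baseline = 2, nb_dispersion = 0.5,
                             dropout_prob = 0.3,
                             mito_fraction_target = 0.05,
                             cycling_fraction = 0.072,
                             partial_emt_fraction = 0.30,
                             cta_detect_prob = 0.02,
                             csc_positive_rates = c(PROM1 = 0.02,
                                                    CD44 = 0.25,
                                                    ALDH1A1 = 0.15,
                                                    ALDH1A3 = 0.05,
                                                    ALDH3A1 = 0.05,
                                                    ABCG2 = 0.01),
                             n_patient_program_genes = 30,
                             programs = c("full", "minimal"),
                             seed = 0) {
  programs <- match.arg(programs)
  cfg <- list(n_patients = as.integer(n_patients),
              cells_per_patient = as.integer(cells_per_patient),
              n_genes = as.integer(n_genes), composition = composition,
              delta = delta, background_log2 = background_log2,
              nb_mean_baseline = nb_mean_baseline,
              nb_dispersion = nb_dispersion, dropout_prob = dropout_prob,
              mito_fraction_target = mito_fraction_target,
              cycling_fraction = cycling_fraction,
              partial_emt_fraction = partial_emt_fraction,
              cta_detect_prob = cta_detect_prob,
              csc_positive_rates = csc_positive_rates,
              n_patient_program_genes = as.integer(n_patient_program_genes),
              programs = programs, seed = as.integer(seed))
  if (cfg$n_patients < 1 || cfg$cells_per_patient < 1) {
    validation_error("need at least one patient and one cell per patient")
  }
  if (!setequal(names(composition), c("T", "B", "monocyte", "CTC"))) {
    validation_error("composition must name T, B, monocyte and CTC")
  }
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-8) {
    validation_error("composition fractions must be non-negative and sum to 1")
  }
  probs <- c(cfg$dropout_prob, cfg$mito_fraction_target,
             cfg$cycling_fraction, cfg$partial_emt_fraction,
             cfg$cta_detect_prob, cfg$csc_positive_rates)
  if (any(probs < 0 | probs >= 1) || any(c(cfg$cycling_fraction,
                                           cfg$partial_emt_fraction) > 1)) {
    validation_error("all rates must be valid probabilities")
  }
  if (cfg$nb_mean_baseline <= 0 || cfg$nb_dispersion <= 0) {
    validation_error("nb_mean_baseline and nb_dispersion must be positive")
  }
  class(cfg) <- "SyntheticConfig"
  synth_gene_universe(cfg)  # errors when n_genes cannot hold the programs
  cfg
}

# Build the simulated gene universe and the program index sets.
synth_gene_universe <- function(cfg) {
  panels <- default_marker_panels()
  emt <- default_emt_sets()
  if (cfg$programs == "full") {
    cc <- default_cycle_genes()
    imm <- default_immune_signature()$immune_signature
    cta <- default_cta_catalog()$CTA
  } else {
    cc <- list(G1S = character(), G2M = character())
    imm <- character()
    cta <- character()
  }
  csc <- if (cfg$programs == "full") csc_markers() else character()
  # the shared immune program must not contain any population-defining
  # panel gene, otherwise the panels lose their discriminating power
  imm_shared <- setdiff(imm, c(panels$T, panels$B, panels$monocyte))
  prog <- list(
    T = union(panels$T, c(panels$leukocyte, imm_shared)),
    B = union(panels$B, c(panels$leukocyte, imm_shared)),
    monocyte = union(panels$monocyte, c(panels$leukocyte, imm_shared)),
    CTC = if (cfg$programs == "full") {
      Reduce(union, list(emt$epithelial, panels$lung,
                         panels$proliferation, emt$ecm))
    } else {
      Reduce(union, list(panels$epithelial, panels$lung,
                         panels$proliferation))
    },
    G1S = cc$G1S, G2M = cc$G2M,
    mes_csc = if (cfg$programs == "full") emt$mes_csc else character()
  )
  # genes whose counts come only from planted Bernoulli detection gates
  gate_cta <- setdiff(cta, c(unlist(prog), csc))
  gate_csc <- setdiff(csc, unlist(prog))      # CD44 stays with mes_csc
  program_gene_pool <- unique(unlist(prog))
  mito <- mito_gene_names()
  special <- unique(c(program_gene_pool, gate_cta, gate_csc, mito))
  n_pat_prog <- cfg$n_patients * cfg$n_patient_program_genes
  n_filler <- cfg$n_genes - length(special) - n_pat_prog
  if (n_filler < 0) {
    validation_error(sprintf(
      "n_genes = %d is too small: %d program/mito genes plus %d patient-program genes are needed",
      cfg$n_genes, length(special), n_pat_prog))
  }
  pat_prog <- lapply(seq_len(cfg$n_patients), function(p) {
    sprintf("PTPROG%d-%03d", p, seq_len(cfg$n_patient_program_genes))
  })
  names(pat_prog) <- paste0("P", seq_len(cfg$n_patients))
  filler <- sprintf("GENE%05d", seq_len(max(n_filler, 0)))
  gene_ids <- c(special, unlist(pat_prog), filler)
  list(gene_ids = gene_ids, programs = prog, patient_programs = pat_prog,
       gate_cta = gate_cta, gate_csc = gate_csc, mito = mito,
       filler = filler, csc = csc)
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws cell labels and state flags from the configured fractions, builds
#' per-cell, per-gene negative-binomial means from the planted programs,
#' simulates counts with dropout, plants gate-driven CTA/CSC detections at
#' their net rates, and calibrates mitochondrial gene means per cell so
#' the expected mitochondrial fraction matches the target. Fully
#' reproducible given the config seed.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return List with elements \code{counts} (a \code{CountMatrix}) and
#'   \code{truth} (a \code{SyntheticTruth} list: per-cell data.frame
#'   \code{cell}, per-gene data.frame \code{gene}, the program gene lists
#'   and the config).
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  uni <- synth_gene_universe(config)
  gene_ids <- uni$gene_ids
  n_genes <- length(gene_ids)
  n_cells <- config$n_patients * config$cells_per_patient
  patients <- rep(paste0("P", seq_len(config$n_patients)),
                  each = config$cells_per_patient)
  cell_ids <- sprintf("%s_C%04d", patients,
                      unlist(lapply(seq_len(config$n_patients),
                                    function(i) seq_len(config$cells_per_patient))))

  with_seed(config$seed, {
    pops <- sample(names(config$composition), n_cells, replace = TRUE,
                   prob = config$composition)
    is_ctc <- pops == "CTC"
    cycling <- is_ctc & stats::runif(n_cells) < config$cycling_fraction
    phase <- ifelse(cycling & stats::runif(n_cells) < 0.5, "G1S", "G2M")
    phase[!cycling] <- NA_character_
    partial_emt <- is_ctc & stats::runif(n_cells) < config$partial_emt_fraction

    # log2 mean matrix: baseline everywhere, background offset on program
    # genes, +delta where the program is active
    base_l2 <- log2(config$nb_mean_baseline)
    l2 <- matrix(base_l2, n_genes, n_cells, dimnames = list(gene_ids, cell_ids))
    prog_members <- unique(c(unlist(uni$programs), unlist(uni$patient_programs)))
    prog_rows <- match(prog_members, gene_ids)
    l2[prog_rows, ] <- base_l2 + config$background_log2

    activate <- function(genes, cells_logical) {
      rows <- match(genes, gene_ids)
      l2[rows, cells_logical] <<- base_l2 + config$delta
    }
    activate(uni$programs$T, pops == "T")
    activate(uni$programs$B, pops == "B")
    activate(uni$programs$monocyte, pops == "monocyte")
    activate(uni$programs$CTC, is_ctc)
    if (length(uni$programs$G1S)) {
      activate(uni$programs$G1S, cycling & phase == "G1S")
      activate(uni$programs$G2M, cycling & phase == "G2M")
    }
    activate(uni$programs$mes_csc, partial_emt)
    for (p in names(uni$patient_programs)) {
      activate(uni$patient_programs[[p]], is_ctc & patients == p)
    }

    # gate-only genes carry no NB expression
    gate_rows <- match(c(uni$gate_cta, uni$gate_csc), gene_ids)
    mu <- 2^l2
    if (length(gate_rows)) mu[gate_rows, ] <- 0

    # per-cell mitochondrial calibration: expected mito share = target
    mito_rows <- match(uni$mito, gene_ids)
    t_mito <- config$mito_fraction_target
    nonmito_total <- colSums(mu[-c(mito_rows, gate_rows), , drop = FALSE])
    mu[mito_rows, ] <- matrix(rep(nonmito_total * t_mito / (1 - t_mito) /
                                    length(mito_rows), each = length(mito_rows)),
                              nrow = length(mito_rows))

    counts <- matrix(0L, n_genes, n_cells, dimnames = list(gene_ids, cell_ids))
    nb_rows <- which(rowSums(mu) > 0)
    draws <- stats::rnbinom(length(nb_rows) * n_cells,
                            size = config$nb_dispersion,
                            mu = as.vector(mu[nb_rows, , drop = FALSE]))
    keep <- stats::rbinom(length(draws), 1L, 1 - config$dropout_prob)
    counts[nb_rows, ] <- draws * keep

    # planted CTA detections (net rates, CTC cells only)
    cta_burden_drawn <- integer(n_cells)
    if (length(uni$gate_cta) && any(is_ctc)) {
      rows <- match(uni$gate_cta, gene_ids)
      gate <- matrix(stats::rbinom(length(rows) * sum(is_ctc), 1L,
                                   config$cta_detect_prob),
                     length(rows), sum(is_ctc))
      amp <- matrix(1L + stats::rpois(length(gate), 2), nrow(gate), ncol(gate))
      counts[rows, is_ctc] <- gate * amp
      cta_burden_drawn[is_ctc] <- as.integer(colSums(gate))
    }

    # planted CSC marker positivity (net rates, CTC cells only); CD44 is
    # carried by the mes_csc program above, the gate adds the planted rate
    csc_drawn <- matrix(FALSE, n_cells, length(uni$csc),
                        dimnames = list(cell_ids, uni$csc))
    for (m in uni$csc) {
      rate <- config$csc_positive_rates[[m]]
      if (is.null(rate) || !m %in% gene_ids) next
      gate <- is_ctc & stats::runif(n_cells) < rate
      row <- match(m, gene_ids)
      if (m %in% uni$gate_csc) {
        counts[row, gate] <- 1L + stats::rpois(sum(gate), 2)
      } else {
        counts[row, gate] <- pmax(counts[row, gate], 1L)
      }
      csc_drawn[, m] <- gate
    }

    cell_meta <- data.frame(cell_id = cell_ids, sample_id = patients,
                            patient_id = patients,
                            population_label = NA_character_,
                            stringsAsFactors = FALSE)
    cm <- count_matrix(counts, gene_ids, cell_ids, cell_meta)
    truth <- structure(list(
      cell = data.frame(cell_id = cell_ids, patient_id = patients,
                        population = pops, cycling = cycling, phase = phase,
                        partial_emt = partial_emt,
                        cta_burden_drawn = cta_burden_drawn,
                        stringsAsFactors = FALSE),
      gene = data.frame(gene_id = gene_ids,
                        base_mean = config$nb_mean_baseline,
                        dispersion = config$nb_dispersion,
                        is_filler = gene_ids %in% uni$filler,
                        stringsAsFactors = FALSE),
      programs = uni$programs,
      patient_programs = uni$patient_programs,
      cta_genes = uni$gate_cta,
      csc_drawn = csc_drawn,
      mito_genes = uni$mito,
      config = config), class = "SyntheticTruth")
    list(counts = cm, truth = truth)
  })
}

#' Named synthetic fixtures
#'
#' \code{tiny}: 50 genes x 30 cells with minimal programs, for unit tests.
#' \code{default}: 2000 genes x 600 cells, one patient, mirroring the
#' per-patient scale of a CSF cohort. \code{cohort}: five patients of 200
#' cells each with patient-private programs.
#'
#' @param name fixture name.
#' @param seed integer seed (default 0).
#' @return As \code{\link{generate_synthetic}}.
#' @export
make_fixture <- function(name = c("tiny", "default", "cohort"), seed = 0) {
  if (!is.character(name) || !name[1] %in% c("tiny", "default", "cohort")) {
    validation_error(sprintf("unknown fixture name: %s",
                             paste(name[1], collapse = "")))
  }
  name <- match.arg(name)
  cfg <- switch(name,
    tiny = synthetic_config(n_patients = 1, cells_per_patient = 30,
                            n_genes = 50, programs = "minimal",
                            n_patient_program_genes = 0, seed = seed),
    default = synthetic_config(n_patients = 1, cells_per_patient = 600,
                               n_genes = 2000, seed = seed),
    cohort = synthetic_config(n_patients = 5, cells_per_patient = 200,
                              n_genes = 2000, seed = seed))
  generate_synthetic(cfg)
}
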