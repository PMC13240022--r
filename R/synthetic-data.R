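#' Design for a synthetic single-cell dataset with planted regulatory structure
#'
#' Describes the simulated study: cells split across terminal fate states,
#' a gene pool containing transcription factors and their target sets
#' (regulons), and a subset of regulons planted as state-specific so that
#' downstream specificity scoring and selection can be checked against known
#' truth. Defaults mirror a mid-sized malignant-hepatocyte subset: three
#' terminal states at unequal proportions, several samples mixed across
#' states, and tens of regulons of 10-25 targets.
#'
#' @param n_cells number of cells.
#' @param n_genes number of genes (includes the TF genes).
#' @param n_states number of terminal fate states, labeled `fate0`, `fate1`, ...
#' @param n_samples number of samples (batches).
#' @param n_tissues number of tissue types.
#' @param n_regulons total number of regulons (one TF each).
#' @param n_state_specific_per_state regulons planted as specific to each state.
#' @param regulon_size_range integer range (min, max) of targets per regulon.
#' @param activity_noise_sd log-scale expression noise standard deviation;
#'   0 gives noise-free, fully separated planted effects.
#' @param effect_shift log-scale upshift of a planted regulon's targets in its
#'   home state's cells.
#' @param state_proportions state mixing proportions (must sum to 1).
#' @param driver_overlap_fraction default fraction of planted targets emitted
#'   as sub-threshold fate drivers by [generate_fate_drivers()].
#' @param n_hubs_per_state planted high-out-degree TFs per state (their
#'   regulons extend five targets beyond the upper size bound).
#' @param confounded_batch if `TRUE`, sample labels follow state labels
#'   (deliberately poor mixing); off by default.
#' @param seed integer seed; all outputs are deterministic given it.
#'
#' @return a validated `synthetic_design` list.
#' @export
synthetic_design <- function(n_cells = 3000L,
                             n_genes = 1000L,
                             n_states = 3L,
                             n_samples = 4L,
                             n_tissues = 3L,
                             n_regulons = 100L,
                             n_state_specific_per_state = 10L,
                             regulon_size_range = c(10L, 25L),
                             activity_noise_sd = 0.5,
                             effect_shift = 1.0,
                             state_proportions = NULL,
                             driver_overlap_fraction = 0.8,
                             n_hubs_per_state = 2L,
                             confounded_batch = FALSE,
                             seed = 1L) {
  d <- list(
    n_cells = check_count(n_cells, "n_cells"),
    n_genes = check_count(n_genes, "n_genes"),
    n_states = check_count(n_states, "n_states"),
    n_samples = check_count(n_samples, "n_samples"),
    n_tissues = check_count(n_tissues, "n_tissues"),
    n_regulons = check_count(n_regulons, "n_regulons"),
    n_state_specific_per_state = check_count(n_state_specific_per_state,
                                             "n_state_specific_per_state"),
    regulon_size_range = regulon_size_range,
    activity_noise_sd = activity_noise_sd,
    effect_shift = as.numeric(effect_shift),
    driver_overlap_fraction = check_fraction(driver_overlap_fraction,
                                             "driver_overlap_fraction"),
    n_hubs_per_state = check_count(n_hubs_per_state, "n_hubs_per_state"),
    confounded_batch = isTRUE(confounded_batch),
    seed = as.integer(seed)
  )
  if (length(regulon_size_range) != 2L || any(regulon_size_range < 1) ||
      regulon_size_range[1] > regulon_size_range[2])
    stop_param("regulon_size_range", "must be an increasing positive pair")
  d$regulon_size_range <- as.integer(regulon_size_range)
  if (length(activity_noise_sd) != 1L || !is.finite(activity_noise_sd) ||
      activity_noise_sd < 0)
    stop_param("activity_noise_sd", "must be a non-negative number")
  d$activity_noise_sd <- as.numeric(activity_noise_sd)
  if (d$n_state_specific_per_state * d$n_states > d$n_regulons)
    stop_param("n_state_specific_per_state",
               "n_state_specific_per_state * n_states must not exceed n_regulons")
  if (d$n_hubs_per_state > d$n_state_specific_per_state)
    stop_param("n_hubs_per_state",
               "must not exceed n_state_specific_per_state")
  if (is.null(state_proportions)) {
    # default unequal groups; stated defaults for 3 states, else uniform
    state_proportions <- if (d$n_states == 3L) c(0.40, 0.35, 0.25)
                         else rep(1 / d$n_states, d$n_states)
  }
  if (length(state_proportions) != d$n_states ||
      any(!is.finite(state_proportions)) || any(state_proportions <= 0) ||
      abs(sum(state_proportions) - 1) > 1e-8)
    stop_param("state_proportions",
               "must be positive, one per state, and sum to 1")
  d$state_proportions <- as.numeric(state_proportions)
  if (2L * d$regulon_size_range[2] * d$n_regulons > 0 &&
      d$n_regulons + d$n_genes < d$n_regulons)  # overflow guard, never triggers
    stop_param("n_genes", "inconsistent")
  class(d) <- "synthetic_design"
  d
}

#' Generate a synthetic single-cell dataset with planted state-specific regulons
#'
#' Cells are assigned to terminal states at the design's proportions. Every
#' gene draws log-normal expression around a gene-specific baseline; targets
#' of a state-specific regulon are shifted up (on the log scale) in that
#' state's cells only, so planted regulons are genuinely co-upregulated in
#' their home state. Sample labels are drawn independently of state (well
#' mixed) unless `confounded_batch` is set, in which case sample follows
#' state. Embedding coordinates are 2-D Gaussian blobs per state placed on a
#' circle; tissue labels are tied to the embedding blobs so that tissue
#' separation is geometrically meaningful.
#'
#' @param design a [synthetic_design()].
#' @return list with `expression` (cells x genes matrix), `cells` (data.frame:
#'   cell, sample, tissue, state, emb1, emb2), `regulons` (named list of
#'   target-gene character vectors; names are TF gene names), and `truth`
#'   (list: `state_specific_regulons` mapping state -> regulon names,
#'   `hub_tfs` mapping state -> TF names, `planted_targets` mapping
#'   state -> target genes of its planted regulons).
#' @export
generate_single_cell_dataset <- function(design) {
  if (!inherits(design, "synthetic_design"))
    stop_param("design", "must be created by synthetic_design()")
  d <- design
  with_seed(d$seed, {
    genes <- sprintf("g%04d", seq_len(d$n_genes))
    tf_idx <- seq_len(d$n_regulons)                 # first genes double as TFs
    tfs <- genes[tf_idx]
    states <- sprintf("fate%d", seq_len(d$n_states) - 1L)

    # regulon sizes; hub regulons sit above the ordinary size range
    sizes <- sample(seq(d$regulon_size_range[1], d$regulon_size_range[2]),
                    d$n_regulons, replace = TRUE)
    target_pool <- genes[-tf_idx]
    spec_idx <- matrix(seq_len(d$n_state_specific_per_state * d$n_states),
                       nrow = d$n_states, byrow = TRUE)
    hub_idx <- spec_idx[, seq_len(d$n_hubs_per_state), drop = FALSE]
    sizes[as.vector(hub_idx)] <- d$regulon_size_range[2] + 5L

    # planted regulons draw targets from per-state disjoint chunks of the
    # pool so that a planted program is up-regulated in one state only;
    # background regulons draw from the whole pool
    chunk_size <- floor(length(target_pool) / (d$n_states + 1L))
    if (max(sizes[as.vector(spec_idx)]) > chunk_size)
      stop_param("n_genes", "too few genes for disjoint state-specific programs")
    chunks <- split(target_pool[seq_len(chunk_size * d$n_states)],
                    rep(seq_len(d$n_states), each = chunk_size))
    chunk_of <- integer(d$n_regulons)
    for (s in seq_len(d$n_states)) chunk_of[spec_idx[s, ]] <- s
    regulons <- lapply(seq_len(d$n_regulons), function(i) {
      pool_i <- if (chunk_of[i] > 0) chunks[[chunk_of[i]]] else target_pool
      sample(pool_i, sizes[i])
    })
    names(regulons) <- tfs

    state_specific <- lapply(seq_len(d$n_states), function(s) {
      tfs[spec_idx[s, ]]
    })
    names(state_specific) <- states
    hub_tfs <- lapply(seq_len(d$n_states), function(s) tfs[hub_idx[s, ]])
    names(hub_tfs) <- states

    # cell state assignment at the stated proportions (exact counts, shuffled)
    counts <- floor(d$state_proportions * d$n_cells)
    rem <- d$n_cells - sum(counts)
    if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
    state <- sample(rep(states, counts))

    sample_lab <- if (d$confounded_batch) {
      sprintf("S%d", (match(state, states) - 1L) %% d$n_samples + 1L)
    } else {
      sprintf("S%d", sample.int(d$n_samples, d$n_cells, replace = TRUE))
    }

    # embedding: Gaussian blob per state on a circle of radius 6
    ang <- 2 * pi * (seq_len(d$n_states) - 1L) / d$n_states
    cx <- 6 * cos(ang); cy <- 6 * sin(ang)
    si <- match(state, states)
    emb1 <- cx[si] + stats::rnorm(d$n_cells, sd = 0.8)
    emb2 <- cy[si] + stats::rnorm(d$n_cells, sd = 0.8)
    # tissues follow the blobs (state-linked) so separation scores are low
    tissue <- sprintf("T%d", (si - 1L) %% d$n_tissues + 1L)

    # expression: log-normal around gene baselines, planted shift per state
    base <- stats::runif(d$n_genes, 0.2, 1.2)       # log-scale baselines
    logmu <- matrix(rep(base, each = d$n_cells), nrow = d$n_cells)
    for (s in seq_len(d$n_states)) {
      tf_s <- state_specific[[s]]
      tgt <- unique(c(tf_s, unlist(regulons[tf_s], use.names = FALSE)))
      gi <- match(tgt, genes)
      ci <- which(si == s)
      logmu[ci, gi] <- logmu[ci, gi] + d$effect_shift
    }
    noise <- if (d$activity_noise_sd > 0)
      matrix(stats::rnorm(d$n_cells * d$n_genes, sd = d$activity_noise_sd),
             nrow = d$n_cells)
    else 0
    expr <- round(exp(logmu + noise), 4)
    dimnames(expr) <- list(sprintf("cell%05d", seq_len(d$n_cells)), genes)

    cells <- data.frame(
      cell = rownames(expr),
      sample = sample_lab,
      tissue = tissue,
      state = state,
      emb1 = emb1,
      emb2 = emb2,
      stringsAsFactors = FALSE
    )
    truth <- list(
      state_specific_regulons = state_specific,
      hub_tfs = hub_tfs,
      planted_targets = lapply(state_specific, function(tf_s)
        unique(unlist(regulons[tf_s], use.names = FALSE)))
    )
    list(expression = expr, cells = cells, regulons = regulons, truth = truth)
  })
}

#' Emit a per-fate fate-driver table with a controlled planted overlap
#'
#' For each fate, a fixed fraction of that fate's planted regulon targets are
#' emitted as drivers with FDR below 0.05 (drawn from `fdr_range`); the rest
#' of the table is filled with decoys — genes outside the planted sets, or
#' left-out planted targets — carrying FDR at or above 0.05. Filtering the
#' table at FDR < 0.05 therefore recovers exactly `round(overlap_fraction * n)`
#' planted targets per fate.
#'
#' @param truth ground-truth list from [generate_single_cell_dataset()].
#' @param regulons named list of regulon target sets.
#' @param fdr_range range of FDR values for true (sub-threshold) drivers.
#' @param overlap_fraction fraction of each fate's planted targets emitted as
#'   sub-threshold drivers.
#' @param n_decoys_per_fate decoy rows added per fate.
#' @param seed integer seed.
#' @return data.frame with columns `gene`, `fate`, `fdr`.
#' @export
generate_fate_drivers <- function(truth, regulons,
                                  fdr_range = c(0.001, 0.049),
                                  overlap_fraction = 0.8,
                                  n_decoys_per_fate = 50L,
                                  seed = 1L) {
  if (length(regulons) == 0L)
    stop("input error: empty regulon set", call. = FALSE)
  check_fraction(overlap_fraction, "overlap_fraction")
  if (length(fdr_range) != 2L || any(fdr_range < 0) || fdr_range[1] > fdr_range[2])
    stop_param("fdr_range", "must be an increasing non-negative pair")
  with_seed(seed, {
    all_genes <- unique(c(names(regulons), unlist(regulons, use.names = FALSE)))
    rows <- lapply(names(truth$planted_targets), function(f) {
      planted <- truth$planted_targets[[f]]
      n_true <- round(overlap_fraction * length(planted))
      true_g <- if (n_true > 0) sample(planted, n_true) else character(0)
      left_out <- setdiff(planted, true_g)
      outside <- setdiff(all_genes, planted)
      decoy_g <- c(left_out,
                   sample(outside, min(n_decoys_per_fate, length(outside))))
      data.frame(
        gene = c(true_g, decoy_g),
        fate = f,
        fdr = c(stats::runif(length(true_g), fdr_range[1], fdr_range[2]),
                stats::runif(length(decoy_g), 0.05, 1)),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

#' Simulate a bulk cohort with a latent-score survival effect
#'
#' Each patient carries a standard-normal latent score; every signature gene's
#' expression equals the score plus independent Gaussian noise, background
#' genes are pure noise. Event times are exponential with hazard
#' `h0 * exp(beta * z)`; an exact `round(censoring_rate * n)` random subset is
#' censored at a Uniform(0, t) time, independently of the score.
#'
#' @param n_patients number of patients.
#' @param signature_genes character vector of signature gene names.
#' @param beta log hazard ratio per unit of the latent score.
#' @param censoring_rate fraction of patients censored, in [0, 1).
#' @param n_background_genes extra noise genes.
#' @param noise_sd gene-level noise standard deviation.
#' @param h0 baseline hazard.
#' @param seed integer seed.
#' @return list with `expression` (genes x patients matrix), `survival`
#'   (data.frame: patient, time, event, stage, age), and `latent` (the true
#'   per-patient score).
#' @export
generate_survival_cohort <- function(n_patients, signature_genes, beta,
                                     censoring_rate = 0.3,
                                     n_background_genes = 100L,
                                     noise_sd = 1.0, h0 = 0.02, seed = 1L) {
  check_count(n_patients, "n_patients")
  if (length(beta) != 1L || !is.finite(beta))
    stop_param("beta", "must be a finite number")
  if (length(censoring_rate) != 1L || !is.finite(censoring_rate) ||
      censoring_rate < 0 || censoring_rate >= 1)
    stop_param("censoring_rate", "must be in [0, 1)")
  with_seed(seed, {
    z <- stats::rnorm(n_patients)
    genes <- c(signature_genes,
               sprintf("bg%04d", seq_len(n_background_genes)))
    expr <- rbind(
      matrix(rep(z, each = length(signature_genes)),
             nrow = length(signature_genes)) +
        matrix(stats::rnorm(length(signature_genes) * n_patients, sd = noise_sd),
               nrow = length(signature_genes)),
      matrix(stats::rnorm(n_background_genes * n_patients),
             nrow = n_background_genes)
    )
    patients <- sprintf("P%04d", seq_len(n_patients))
    dimnames(expr) <- list(genes, patients)

    t_event <- stats::rexp(n_patients, rate = h0 * exp(beta * z))
    event <- rep(1L, n_patients)
    n_cens <- round(censoring_rate * n_patients)
    if (n_cens > 0) {
      ci <- sample.int(n_patients, n_cens)
      event[ci] <- 0L
      t_event[ci] <- stats::runif(n_cens, 0, t_event[ci])
    }
    surv <- data.frame(
      patient = patients,
      time = round(t_event, 4),
      event = event,
      stage = sample(c("I", "II", "III", "IV"), n_patients, replace = TRUE,
                     prob = c(0.45, 0.25, 0.25, 0.05)),
      age = round(stats::runif(n_patients, 35, 85)),
      stringsAsFactors = FALSE
    )
    list(expression = expr, survival = surv, latent = z)
  })
}

#' Simulate a directed TF-target network with planted hubs
#'
#' Builds a random regulatory graph in which a few designated hub TFs receive
#' a top-decile out-degree and the remaining TFs draw small target sets; used
#' to exercise topology metrics and composite hub scoring against known hubs.
#'
#' @param n_nodes total node count (TFs + targets).
#' @param n_tfs number of TF nodes.
#' @param n_hubs number of planted hub TFs.
#' @param seed integer seed.
#' @return list with `edges` (data.frame: from, to) and `hubs` (hub TF names).
#' @export
simulate_hub_network <- function(n_nodes = 40L, n_tfs = 8L, n_hubs = 2L,
                                 seed = 1L) {
  check_count(n_nodes, "n_nodes")
  n_tfs <- check_count(n_tfs, "n_tfs")
  n_hubs <- check_count(n_hubs, "n_hubs")
  if (n_hubs > n_tfs || n_tfs >= n_nodes)
    stop_param("n_tfs", "need n_hubs <= n_tfs < n_nodes")
  with_seed(seed, {
    tfs <- sprintf("TF%02d", seq_len(n_tfs))
    tgts <- sprintf("t%03d", seq_len(n_nodes - n_tfs))
    n_t <- length(tgts)
    hub_deg <- max(3L, ceiling(0.6 * n_t))
    bg_deg_max <- max(2L, floor(0.2 * n_t))
    edges <- lapply(seq_len(n_tfs), function(i) {
      if (i <= n_hubs) {
        # hubs regulate a top-decile share of targets; the remaining TFs
        # also feed into the hubs, so hubs carry through-path betweenness
        data.frame(from = tfs[i], to = sample(tgts, min(hub_deg, n_t)),
                   stringsAsFactors = FALSE)
      } else {
        k <- sample(seq(1L, bg_deg_max), 1L)
        data.frame(from = tfs[i],
                   to = c(sample(tgts, min(k, n_t)),
                          tfs[seq_len(n_hubs)]),
                   stringsAsFactors = FALSE)
      }
    })
    edges <- unique(do.call(rbind, edges))
    list(edges = edges, hubs = tfs[seq_len(n_hubs)])
  })
}
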