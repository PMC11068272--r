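#' Simulate a heterochronous coalescent genealogy
#'
#' Exact inversion sampling under the inhomogeneous exponential law with
#' rate `k(k-1)/(2 Ne(t))`: a standard exponential deviate is inverted
#' against the cumulative hazard accumulated segment by segment, where
#' segments are delimited by sampling events and trajectory change-points
#' (within a constant segment the waiting time is `2 rho E / (k(k-1))`;
#' within a linear segment `Ne(a) (exp(2 alpha E / (k(k-1))) - 1)/alpha`).
#' The coalescing pair is chosen uniformly.
#'
#' @param sampling_ages numeric sampling ages (time before present,
#'   `>= 0`), optionally named with tip labels (defaults `t1 ... tn`).
#' @param traj a [trajectory].
#' @return a [genealogy].
#' @export
#' @examples
#' set.seed(1)
#' g <- simulate_genealogy(rep(0, 5), trajectory(0, 1000))
simulate_genealogy <- function(sampling_ages, traj) {
  stopifnot(inherits(traj, "demographic_trajectory"))
  n <- length(sampling_ages)
  if (n < 2) stop("need at least two samples")
  if (any(sampling_ages < 0)) stop("sampling ages must be >= 0")
  labels <- names(sampling_ages)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  ages <- as.numeric(sampling_ages)

  ord <- order(ages)
  pending <- ord                     # tip indices not yet sampled, by age
  nnode <- n - 1L
  ntot <- n + nnode
  node_time <- c(ages, rep(NA_real_, nnode))
  edge <- matrix(NA_integer_, nrow = 2L * nnode, ncol = 2)
  edge_len <- numeric(2L * nnode)
  next_node <- n + 1L
  n_edge <- 0L

  cur_t <- ages[pending[1]]
  active <- integer(0)
  target <- stats::rexp(1)           # E ~ Exp(1), inverted through segments
  repeat {
    while (length(pending) > 0 && ages[pending[1]] <= cur_t) {
      active <- c(active, pending[1])
      pending <- pending[-1]
    }
    k <- length(active)
    if (k == 1 && length(pending) == 0) break
    if (k < 2) {                     # wait for the next sampling event
      cur_t <- ages[pending[1]]
      next
    }
    ## hazard is accumulated across sampling events with the realized k(t):
    ## the remaining target stays Exp(1) by memorylessness
    stop_t <- if (length(pending) > 0) ages[pending[1]] else Inf
    haz <- if (is.finite(stop_t))
      cumulative_hazard(traj, cur_t, stop_t, k) else Inf
    if (haz < target) {              # next sampling event comes first
      target <- target - haz
      cur_t <- stop_t
      next
    }
    cur_t <- invert_hazard(traj, cur_t, k, target)
    target <- stats::rexp(1)
    pair <- sample.int(k, 2)
    node_time[next_node] <- cur_t
    for (ch in active[pair]) {
      n_edge <- n_edge + 1L
      edge[n_edge, ] <- c(next_node, ch)
      edge_len[n_edge] <- cur_t - node_time[ch]
    }
    active <- c(active[-pair], next_node)
    next_node <- next_node + 1L
    if (length(active) == 1 && length(pending) == 0) break
  }

  ## renumber internal nodes so the root (oldest, created last) is n + 1,
  ## as ape expects, with the rest in decreasing age order
  internal <- (n + 1L):ntot
  remap <- integer(ntot)
  remap[seq_len(n)] <- seq_len(n)
  remap[internal[order(node_time[internal], decreasing = TRUE)]] <-
    internal
  edge[] <- remap[edge]
  phy <- structure(list(edge = edge, edge.length = edge_len,
                        tip.label = labels, Nnode = nnode),
                   class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  genealogy(phy, stats::setNames(ages, labels))
}

## cumulative hazard over (a, b) with k lineages, split at change-points
cumulative_hazard <- function(traj, a, b, k) {
  if (b <= a || k < 2) return(0)
  cuts <- traj$x[traj$x > a & traj$x < b]
  lo <- c(a, cuts); hi <- c(cuts, b)
  sum(segment_hazards(lo, hi, rep(k, length(lo)), traj))
}

## solve integral_a^{a+w} k(k-1)/(2 Ne(t)) dt = target for w, where no
## sampling event intervenes; change-points are crossed analytically
invert_hazard <- function(traj, a, k, target) {
  kk2 <- k * (k - 1) / 2
  L <- length(traj$x)
  cur <- a
  repeat {
    i <- findInterval(cur, traj$x)
    upper <- if (i < L) traj$x[i + 1] else Inf
    if (traj$mode == "constant" || i >= L) {
      rho <- traj$rho[min(i, L)]
      w <- target * rho / kk2
      if (!is.finite(upper) || cur + w <= upper) return(cur + w)
      target <- target - kk2 * (upper - cur) / rho
    } else {
      alpha <- (traj$rho[i + 1] - traj$rho[i]) / (traj$x[i + 1] - traj$x[i])
      ne_cur <- traj$rho[i] + (cur - traj$x[i]) * alpha
      if (alpha == 0) {
        w <- target * ne_cur / kk2
        if (cur + w <= upper) return(cur + w)
        target <- target - kk2 * (upper - cur) / ne_cur
      } else {
        w <- ne_cur * expm1(alpha * target / kk2) / alpha
        if (cur + w <= upper) return(cur + w)
        ne_up <- traj$rho[i] + (upper - traj$x[i]) * alpha
        target <- target - kk2 / alpha * log(ne_up / ne_cur)
      }
    }
    cur <- upper
  }
}

#' Simulate a nucleotide alignment on a genealogy (Jukes-Cantor)
#'
#' Sites evolve independently down the topology under the Jukes-Cantor
#' model: along a branch of duration `t` a site differs from its ancestor
#' with probability `3/4 (1 - exp(-4 mu t / 3))`.
#'
#' @param g a [genealogy].
#' @param mutation_rate substitution rate per site per time unit (`>= 0`).
#' @param seq_length number of sites (`>= 1`).
#' @return a character matrix (tips x sites, rownames = tip labels) of
#'   `A/C/G/T`.
#' @export
simulate_alignment <- function(g, mutation_rate, seq_length) {
  stopifnot(inherits(g, "genealogy"))
  if (mutation_rate < 0) stop("mutation_rate must be >= 0")
  seq_length <- as.integer(seq_length)
  if (seq_length < 1) stop("seq_length must be >= 1")
  bases <- c("A", "C", "G", "T")
  phy <- g$phy
  n <- length(phy$tip.label)
  ntot <- n + phy$Nnode
  root <- n + 1L
  seqs <- matrix(NA_integer_, nrow = ntot, ncol = seq_length)
  seqs[root, ] <- sample.int(4, seq_length, replace = TRUE)
  ## preorder: parents are assigned before children
  po <- ape::reorder.phylo(phy, "cladewise")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]; chi <- po$edge[e, 2L]
    p_diff <- 0.75 * (1 - exp(-4 * mutation_rate * po$edge.length[e] / 3))
    s <- seqs[par, ]
    hit <- stats::runif(seq_length) < p_diff
    if (any(hit)) {
      shift <- sample.int(3, sum(hit), replace = TRUE)
      s[hit] <- ((s[hit] - 1L + shift) %% 4L) + 1L
    }
    seqs[chi, ] <- s
  }
  out <- matrix(bases[seqs[seq_len(n), , drop = FALSE]], nrow = n)
  rownames(out) <- phy$tip.label
  out
}

#' Write an alignment as FASTA
#'
#' @param aln character matrix from [simulate_alignment()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", rownames(aln)[i]), con)
    writeLines(paste(aln[i, ], collapse = ""), con)
  }
  invisible(path)
}

## truth trajectories for the fixture scenarios: a constant history and a
## variable one with a recent peak (the two qualitative shapes contrasted
## in the simulation design)
fixture_truth <- function(scenario) {
  switch(scenario,
    constant_truth = ,
    isochronous36 = ,
    heterochronous173 = trajectory(0, 1e5),
    bsp_like_truth = trajectory(c(0, 5000, 25000, 60000),
                                c(8e4, 2.5e5, 8e4, 1.2e5)),
    stop("unknown scenario: ", scenario))
}

#' Generate packaged-shape simulation fixtures
#'
#' Writes genealogies (Newick, one per line), a tip-age table, alignments
#' (FASTA) and the true trajectory for one of four scenarios:
#' `isochronous36` (36 tips at the present), `heterochronous173` (173 tips,
#' 137 with ages drawn uniformly on (0, 50000)), `constant_truth` and
#' `bsp_like_truth` (36-tip replicates under a constant trajectory and a
#' trajectory with a recent peak, respectively).  Sequence fixtures use a
#' 16,000-site Jukes-Cantor alignment with a clock calibrated to roughly 2%
#' pairwise diversity, mimicking a mitochondrial genome.
#'
#' @param scenario one of the four scenario names.
#' @param dir output directory (created if needed).
#' @param n_replicates number of simulated genealogies (default 1; the
#'   truth-scenario designs use 10).
#' @param write_alignments also simulate and write FASTA alignments.
#' @param mutation_rate,seq_length sequence-simulation settings.
#' @return invisibly, a list with the simulated `genealogies`, the `truth`
#'   trajectory and the written file `paths`.
#' @export
make_fixture <- function(scenario = c("isochronous36", "heterochronous173",
                                      "constant_truth", "bsp_like_truth"),
                         dir, n_replicates = NULL, write_alignments = FALSE,
                         mutation_rate = 1e-7, seq_length = 16000) {
  scenario <- match.arg(scenario)
  if (is.null(n_replicates))
    n_replicates <- if (grepl("truth", scenario)) 10L else 1L
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- fixture_truth(scenario)

  ages <- if (scenario == "heterochronous173") {
    stats::setNames(c(rep(0, 36), stats::runif(137, 0, 50000)),
                    paste0("t", seq_len(173)))
  } else {
    stats::setNames(rep(0, 36), paste0("t", seq_len(36)))
  }

  gs <- lapply(seq_len(n_replicates), function(i)
    simulate_genealogy(ages, truth))

  nwk <- file.path(dir, paste0(scenario, ".trees"))
  writeLines(vapply(gs, function(g) ape::write.tree(g$phy, digits = 17), character(1)),
             nwk)
  ages_path <- file.path(dir, paste0(scenario, "_ages.tsv"))
  utils::write.table(
    data.frame(label = names(ages), age = unname(ages)),
    ages_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_path <- file.path(dir, paste0(scenario, "_truth.tsv"))
  write_trajectory(truth, truth_path)
  paths <- list(trees = nwk, ages = ages_path, truth = truth_path)

  if (write_alignments) {
    paths$fasta <- vapply(seq_len(n_replicates), function(i) {
      p <- file.path(dir, sprintf("%s_rep%02d.fasta", scenario, i))
      write_alignment(simulate_alignment(gs[[i]], mutation_rate, seq_length), p)
      p
    }, character(1))
  }
  invisible(list(genealogies = gs, truth = truth, paths = paths))
}
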