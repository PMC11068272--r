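#' Genealogies with dated tips
#'
#' A `genealogy` is a rooted, binary, time-calibrated tree in which every node
#' carries a time *before the present*: tips sit at their sampling ages
#' (`0` for contemporaneous samples) and internal nodes at coalescent times.
#' Time runs backward, increasing into the past, and all times share the
#' units of the input tree (generations or calendar years); the package never
#' rescales.  Following the usual convention for serially sampled data, the
#' coalescent times are indexed so that `t[1]` is the most recent coalescent
#' event and `t[n-1]` the root (the time of the most recent common ancestor).
#'
#' @param phy an [ape::phylo] object, rooted and binary, with branch lengths.
#' @param tip_ages named numeric vector of sampling ages (time before
#'   present, `>= 0`), one per tip label; or a two-column data frame
#'   `(label, age)`.
#' @param tol relative tolerance for tip-age/branch-length consistency.
#'
#' @return an object of class `genealogy`: a list with elements
#'   `phy` (the tree), `tip_ages` (named vector, ordered as `phy$tip.label`),
#'   `node_times` (time before present for every node, tips first),
#'   and `coal_times` (the `n - 1` coalescent times, sorted increasing).
#' @export
genealogy <- function(phy, tip_ages, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop("'phy' must be an ape \"phylo\" object")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch length")
  if (!ape::is.binary(phy)) stop("tree must be strictly binary (no multifurcations)")
  n <- length(phy$tip.label)
  if (n < 2) stop("need at least two tips")

  ages <- as_tip_ages(tip_ages)
  missing <- setdiff(phy$tip.label, names(ages))
  if (length(missing) > 0)
    stop("no age given for tip(s): ", paste(missing, collapse = ", "))
  unknown <- setdiff(names(ages), phy$tip.label)
  if (length(unknown) > 0)
    stop("unknown tip label(s) in age table: ", paste(unknown, collapse = ", "))
  ages <- ages[phy$tip.label]
  if (any(ages < 0)) stop("sampling ages must be >= 0")

  nnode <- phy$Nnode
  ntot <- n + nnode
  node_times <- rep(NA_real_, ntot)
  node_times[seq_len(n)] <- ages

  ## postorder: children are dated before their parent; the parent time is
  ## child time + branch length, checked for consistency across both children
  po <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]
    chi <- po$edge[e, 2L]
    tv <- node_times[chi] + po$edge.length[e]
    if (is.na(node_times[par])) {
      node_times[par] <- tv
    } else {
      scale <- max(abs(node_times[par]), abs(tv), 1)
      if (abs(node_times[par] - tv) > tol * scale)
        stop(sprintf(
          "tip ages inconsistent with branch lengths at node %d (%.9g vs %.9g)",
          par, node_times[par], tv))
    }
  }
  ## every internal node must be strictly older than both of its children
  if (any(node_times[po$edge[, 1L]] <= node_times[po$edge[, 2L]]))
    stop("zero-length branch: internal nodes must be strictly older than their children")
  coal_times <- sort(node_times[(n + 1L):ntot])
  structure(
    list(phy = phy, tip_ages = ages, node_times = node_times,
         coal_times = coal_times),
    class = "genealogy")
}

as_tip_ages <- function(tip_ages) {
  if (is.data.frame(tip_ages)) {
    if (ncol(tip_ages) < 2) stop("tip age table needs columns (label, age)")
    ages <- as.numeric(tip_ages[[2]])
    names(ages) <- as.character(tip_ages[[1]])
    ages
  } else if (is.numeric(tip_ages) && !is.null(names(tip_ages))) {
    tip_ages
  } else {
    stop("'tip_ages' must be a named numeric vector or a (label, age) data frame")
  }
}

#' Read a genealogy from Newick text plus a tip-age table
#'
#' The tip ages are authoritative: branch lengths are validated against them
#' (each parent time must equal child time + branch length for both
#' children), and inconsistencies beyond `tol` relative are rejected.
#'
#' @param newick a Newick string, or the path of a file containing one tree.
#' @param tip_ages named numeric vector, data frame `(label, age)`, or the
#'   path of a two-column tab-separated file with a header.
#' @param tol relative tolerance for age/branch-length consistency.
#' @return a [genealogy] object.
#' @export
#' @examples
#' g <- read_genealogy("(A:1,B:1);", c(A = 0, B = 0))
#' g$coal_times  # 1
read_genealogy <- function(newick, tip_ages, tol = 1e-6) {
  phy <- parse_newick(newick)
  if (inherits(phy, "multiPhylo"))
    stop("multiple trees supplied; use read_genealogies()")
  genealogy(phy, read_tip_ages(tip_ages), tol = tol)
}

#' Read several genealogies (one Newick per line) sharing a tip-age table
#'
#' @inheritParams read_genealogy
#' @return a list of [genealogy] objects.
#' @export
read_genealogies <- function(newick, tip_ages, tol = 1e-6) {
  phy <- parse_newick(newick)
  if (inherits(phy, "phylo")) phy <- list(phy)
  ages <- read_tip_ages(tip_ages)
  lapply(phy, function(p) genealogy(p, ages[p$tip.label], tol = tol))
}

parse_newick <- function(newick) {
  if (length(newick) == 1 && !grepl(";", newick) && file.exists(newick)) {
    tr <- ape::read.tree(newick)
  } else {
    tr <- ape::read.tree(text = paste(newick, collapse = "\n"))
  }
  if (is.null(tr)) stop("could not parse Newick input")
  tr
}

read_tip_ages <- function(tip_ages) {
  if (is.character(tip_ages) && length(tip_ages) == 1 && file.exists(tip_ages)) {
    tab <- utils::read.table(tip_ages, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    as_tip_ages(tab)
  } else {
    as_tip_ages(tip_ages)
  }
}

#' Write a genealogy as Newick text plus a tip-age table
#'
#' Round-tripping through [read_genealogy()] reproduces all node times to
#' within 1e-9.
#'
#' @param g a [genealogy].
#' @param newick_file,ages_file optional paths; when given the Newick string
#'   and the tab-separated `(label, age)` table are also written to disk.
#' @return invisibly, a list with `newick` (string) and `tip_ages`
#'   (data frame with columns `label`, `age`).
#' @export
write_genealogy <- function(g, newick_file = NULL, ages_file = NULL) {
  stopifnot(inherits(g, "genealogy"))
  newick <- ape::write.tree(g$phy, digits = 17)
  ages <- data.frame(label = names(g$tip_ages), age = unname(g$tip_ages),
                     stringsAsFactors = FALSE)
  if (!is.null(newick_file)) writeLines(newick, newick_file)
  if (!is.null(ages_file))
    utils::write.table(ages, ages_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(list(newick = newick, tip_ages = ages))
}

#' @export
print.genealogy <- function(x, ...) {
  n <- length(x$tip_ages)
  cat(sprintf("genealogy: %d tips (%s), TMRCA %.6g\n", n,
              if (all(x$tip_ages == 0)) "isochronous" else
                sprintf("heterochronous, %d ancient", sum(x$tip_ages > 0)),
              max(x$coal_times)))
  invisible(x)
}

#' Number of tips of a genealogy
#' @param g a [genealogy].
#' @return integer tip count.
#' @export
n_tips <- function(g) length(g$tip_ages)

#' Build the merged event timeline of a genealogy
#'
#' Merges sampling events, coalescent events and trajectory change-points
#' into one list ordered by time before present, tracking the number of
#' active lineages `k` after each event.  Sampling increases `k` (coincident
#' sampling times are merged into one event), each coalescence decreases `k`
#' by one, and change-points leave `k` unchanged.  Ties at equal times are
#' ordered sampling < coalescent < change-point, so that `k >= 2` holds at
#' any coalescent event in degenerate ties.
#'
#' @param g a [genealogy].
#' @param change_points numeric vector of change-point times (sorted, `>= 0`);
#'   may be empty.
#' @return a data frame of class `event_timeline` with columns `time`,
#'   `type` (factor: `sampling`, `coalescent`, `changepoint`) and `k_after`,
#'   plus attribute `r` (event count).
#' @export
build_timeline <- function(g, change_points = numeric()) {
  stopifnot(inherits(g, "genealogy"))
  if (is.unsorted(change_points)) stop("change_points must be sorted")
  if (length(change_points) > 0 && any(change_points < 0))
    stop("change_points must be >= 0")

  s <- sort(unique(g$tip_ages))
  s_count <- as.numeric(table(factor(g$tip_ages, levels = s)))
  ev_time <- c(s, g$coal_times, change_points)
  ev_type <- c(rep(1L, length(s)), rep(2L, length(g$coal_times)),
               rep(3L, length(change_points)))
  ev_dk <- c(s_count, rep(-1, length(g$coal_times)),
             rep(0, length(change_points)))
  o <- order(ev_time, ev_type)
  tl <- data.frame(
    time = ev_time[o],
    type = factor(c("sampling", "coalescent", "changepoint")[ev_type[o]],
                  levels = c("sampling", "coalescent", "changepoint")),
    k_after = cumsum(ev_dk[o]))
  attr(tl, "r") <- nrow(tl)
  class(tl) <- c("event_timeline", class(tl))
  tl
}
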