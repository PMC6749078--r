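# Hub detection on metastate centrality patterns and weighted rich-club
# analysis of structural networks with degree-preserving nulls.

#' Detect hub regions of a centrality pattern
#'
#' Hubs are regions whose score exceeds mean + `multiplier` * SD (sample SD)
#' of the pattern — the classic one-standard-deviation top-ranking rule.
#'
#' @param pattern Named numeric vector of region scores (>= 2 regions).
#' @param multiplier SD multiplier (default 1).
#' @return Object of class `"hub_set"`: list with `members` (region names),
#'   `threshold_value`, `multiplier`, `scores`.
#' @export
detect_hubs <- function(pattern, multiplier = 1) {
  if (length(pattern) < 2) stopf("need >= 2 regions")
  if (is.null(names(pattern)))
    names(pattern) <- paste0("R", seq_along(pattern))
  s <- stats::sd(pattern)
  if (s == 0) {
    warnf("constant pattern: no hubs definable")
    return(structure(list(members = character(0),
                          threshold_value = mean(pattern),
                          multiplier = multiplier, scores = pattern),
                     class = "hub_set"))
  }
  thr <- mean(pattern) + multiplier * s
  structure(list(members = names(pattern)[pattern > thr],
                 threshold_value = thr, multiplier = multiplier,
                 scores = pattern),
            class = "hub_set")
}

#' @export
print.hub_set <- function(x, ...) {
  cat(sprintf("<hub_set> %d hubs above %.4f (mean + %g SD): %s\n",
              length(x$members), x$threshold_value, x$multiplier,
              paste(x$members, collapse = ", ")))
  invisible(x)
}

#' Overlap rate between a hub set and a region set
#'
#' Fraction of hubs falling inside a reference region set (e.g. an intrinsic
#' sub-network), with the raw "x/y" counts.
#'
#' @param hubs A [detect_hubs()] result or a character vector of regions.
#' @param region_set Character vector of reference region names.
#' @return List with `rate`, `overlap` (count), `n_hubs` and `counts`
#'   (the "x/y" string).
#' @export
overlap_rate <- function(hubs, region_set) {
  members <- if (inherits(hubs, "hub_set")) hubs$members else as.character(hubs)
  if (!length(members)) stopf("empty hub set")
  ov <- length(intersect(members, region_set))
  list(rate = ov / length(members), overlap = ov, n_hubs = length(members),
       counts = sprintf("%d/%d", ov, length(members)))
}

#' Packaged metastate hub lists
#'
#' The hub-region lists of the five reported metastates (sizes 17, 16, 16,
#' 18, 15) plus the structural-network hub list, as AAL-90 region
#' abbreviations.
#'
#' @return Named list of character vectors: `state1`..`state5`,
#'   `structural`.
#' @export
reference_hub_lists <- function() {
  path <- system.file("extdata", "metastate_hub_regions.json",
                      package = "metastate")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @noRd
strength_ranks <- function(W) {
  s <- rowSums(W)
  labs <- rownames(W) %||% as.character(seq_len(nrow(W)))
  order(-s, labs)  # strength descending, ties by label order
}

#' Weighted rich-club coefficient at a rank threshold
#'
#' Nodes are ranked by weighted degree (strength), descending. At rank r the
#' club is the top r nodes; the coefficient is the total edge weight inside
#' the club divided by the sum of the equally many strongest edge weights of
#' the whole network — 1 means the club carries the heaviest edges the
#' network has to offer.
#'
#' @param W Square symmetric weighted matrix, zero diagonal.
#' @param r Rank threshold (club = top r nodes by strength).
#' @return Phi in `[0, 1]`, or `NA` when the club subgraph has no edges.
#' @export
rich_club_coefficient <- function(W, r) {
  assert_square_symmetric(W, "W")
  n <- nrow(W)
  if (!is_count(r) || r < 1 || r > n) stopf("rank r must lie in 1..%d", n)
  club <- strength_ranks(W)[seq_len(r)]
  sub <- W[club, club, drop = FALSE]
  ut <- upper.tri(sub)
  e_gt <- sum(sub[ut] != 0)
  if (e_gt == 0) return(NA_real_)
  w_gt <- sum(sub[ut])
  all_w <- sort(W[upper.tri(W)][W[upper.tri(W)] != 0], decreasing = TRUE)
  w_gt / sum(all_w[seq_len(e_gt)])
}

#' Degree-preserving randomized network
#'
#' Maslov-Sneppen double-edge swaps (10 x edge count attempted swaps) rewire
#' the topology while preserving every node's degree exactly; the original
#' weight multiset is then reassigned to the rewired edges uniformly at
#' random. Graphs admitting no valid swap (e.g. a triangle) are returned
#' unchanged with a warning.
#'
#' @param W Square symmetric weighted matrix, zero diagonal, >= 2 edges.
#' @param seed Integer seed.
#' @return Randomized matrix with identical degree sequence and weight
#'   multiset.
#' @export
degree_preserving_null <- function(W, seed = 1L) {
  assert_square_symmetric(W, "W")
  adj <- W != 0
  m <- sum(adj[upper.tri(adj)])
  if (m < 2) stopf("need >= 2 edges to rewire")
  g <- igraph::graph_from_adjacency_matrix(adj * 1, mode = "undirected")
  out <- with_seed(seed, {
    g2 <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * m))
    a2 <- as.matrix(igraph::as_adjacency_matrix(g2, sparse = FALSE)) != 0
    if (identical(unname(a2), unname(adj)))
      warnf("no degree-preserving rewiring possible; topology unchanged")
    weights <- W[upper.tri(W)][adj[upper.tri(adj)]]
    res <- matrix(0, nrow(W), ncol(W), dimnames = dimnames(W))
    ut_edges <- which(upper.tri(a2) & a2)
    res[ut_edges] <- sample(weights, length(weights))
    res + t(res)
  })
  out
}

#' Normalized weighted rich-club curve
#'
#' Phi(r) for every rank r in `1..(n-2)`, normalized by the mean coefficient
#' of `n_null` degree-preserving, weight-multiset-preserving random networks.
#' A normalized coefficient above 1 at some rank indicates a rich-club
#' effect: the top-strength nodes interconnect more strongly than degree
#' alone explains. Ranks where the null coefficient is undefined for more
#' than half of the draws stay `NA`.
#'
#' @param W Square symmetric weighted matrix, zero diagonal.
#' @param n_null Number of null networks (>= 1; 1000 for the standard
#'   analysis).
#' @param seed Integer seed (each null draw uses a derived sub-seed, so the
#'   curve is reproducible).
#' @return Object of class `"rich_club_curve"`: data frame fields `r_grid`,
#'   `phi`, `phi_rand_mean`, `phi_norm`, plus `n_null` and `seed`.
#' @export
normalized_rich_club <- function(W, n_null = 1000, seed = 1L) {
  assert_square_symmetric(W, "W")
  if (!is_count(n_null) || n_null < 1) stopf("n_null must be >= 1")
  n <- nrow(W)
  if (n < 4) stopf("network too small for a rich-club curve")
  r_grid <- seq_len(n - 2)
  phi <- vapply(r_grid, function(r) rich_club_coefficient(W, r), numeric(1))
  null_phi <- matrix(NA_real_, n_null, length(r_grid))
  for (b in seq_len(n_null)) {
    Wb <- suppressWarnings(degree_preserving_null(W, seed = sub_seed(seed, b)))
    null_phi[b, ] <- vapply(r_grid, function(r) rich_club_coefficient(Wb, r),
                            numeric(1))
  }
  defined_frac <- colMeans(!is.na(null_phi))
  phi_rand <- ifelse(defined_frac > 0.5,
                     colMeans(null_phi, na.rm = TRUE), NA_real_)
  phi_norm <- ifelse(!is.na(phi) & !is.na(phi_rand) & phi_rand > 0,
                     phi / phi_rand, NA_real_)
  structure(list(r_grid = r_grid, phi = phi, phi_rand_mean = phi_rand,
                 phi_norm = phi_norm, n_null = as.integer(n_null),
                 seed = as.integer(seed)),
            class = "rich_club_curve")
}

#' @export
print.rich_club_curve <- function(x, ...) {
  above <- x$r_grid[!is.na(x$phi_norm) & x$phi_norm > 1]
  cat(sprintf("<rich_club_curve> ranks 1..%d, %d nulls; phi_norm > 1 at %d rank(s)%s\n",
              max(x$r_grid), x$n_null, length(above),
              if (length(above)) paste0(" (", paste(utils::head(above, 10),
                                                    collapse = ","), ")") else ""))
  invisible(x)
}

#' @export
as.data.frame.rich_club_curve <- function(x, ...) {
  data.frame(r = x$r_grid, phi = x$phi, phi_rand_mean = x$phi_rand_mean,
             phi_norm = x$phi_norm)
}
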