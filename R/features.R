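#' Feature-point cloud
#'
#' A small set of points (codebook vectors) encoding the shape of a
#' structure or map, as produced by vector quantization. Optional per-point
#' weights and a per-point positional `variability` (spread across repeated
#' quantization runs, a practical estimator of docking accuracy).
#'
#' @param points n x 3 coordinate matrix (Angstrom).
#' @param weights optional nonnegative per-point weights.
#' @param variability optional per-point spread in Angstrom.
#' @return Object of class `point_cloud`.
#' @export
point_cloud <- function(points, weights = NULL, variability = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 1)
  if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(points), all(weights >= 0),
              sum(weights) > 0)
  }
  structure(list(points = points, weights = weights,
                 variability = variability, n = nrow(points)),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points%s\n", x$n,
              if (!is.null(x$variability))
                sprintf(", mean variability %.3g A", mean(x$variability))
              else ""))
  invisible(x)
}

#' Vector quantization of a structure or map into feature points
#'
#' Computes `n` codebook vectors minimizing the weighted squared distortion
#' `sum_i w_i min_k ||x_i - c_k||^2`, where the data are atom positions
#' (unit weights) or positive-density voxel centers (density weights).
#' The quantizer is best-of-`restarts` batch k-means with k-means++-style
#' seeding under a fixed seed; at convergence the nearest-codebook
#' assignment is a fixed point of the update.
#'
#' The per-point `variability` is estimated across the restarts: each run's
#' codebook is matched to the best run's by optimal assignment, and the
#' variability of a point is the mean distance to its matched partners --
#' a practical reproducibility measure used to choose the level of detail.
#'
#' @param source an [atomic_model], bead model, or [volume_map].
#' @param n number of feature points.
#' @param seed integer seed for reproducible restarts.
#' @param restarts number of independent runs (>= 2 for variability).
#' @param iter_max Lloyd iteration cap per run.
#' @return A [point_cloud] with `variability` and attribute `distortion`.
#' @export
vq <- function(source, n, seed = 1, restarts = 5, iter_max = 100) {
  if (inherits(source, "bead_model")) source <- as_atomic_model(source)
  if (inherits(source, "volume_map")) {
    sel <- which(as.vector(source$data) > 0)
    if (length(sel) == 0) stop("map has no positive density")
    x <- voxel_position(source, arrayInd(sel, source$dims) - 1L)
    w <- as.vector(source$data)[sel]
  } else if (inherits(source, "atomic_model")) {
    x <- coords(source)
    w <- rep(1, nrow(x))
  } else stop("source must be an atomic_model, bead_model or volume_map")
  if (n < 1) stop("n must be >= 1")
  if (n > nrow(x)) stop("n = ", n, " exceeds the number of data points (",
                        nrow(x), ")")
  if (all(apply(x, 2, function(v) diff(range(v))) == 0) && n > 1)
    stop("degenerate input: all points identical")
  set.seed(seed)
  runs <- lapply(seq_len(restarts), function(r) kmeans_weighted(x, w, n,
                                                                iter_max))
  best <- which.min(vapply(runs, `[[`, 0, "distortion"))
  cb <- runs[[best]]$centers
  variability <- rep(0, n)
  if (restarts >= 2) {
    for (r in setdiff(seq_len(restarts), best)) {
      d <- outer_dist(cb, runs[[r]]$centers)
      asg <- lap_solve(d)
      variability <- variability + d[cbind(seq_len(n), asg)]
    }
    variability <- variability / (restarts - 1)
  }
  out <- point_cloud(cb, weights = runs[[best]]$mass,
                     variability = variability)
  attr(out, "distortion") <- runs[[best]]$distortion
  out
}

# Weighted batch k-means with k-means++ seeding (squared-distance sampling).
kmeans_weighted <- function(x, w, k, iter_max = 100) {
  n <- nrow(x)
  centers <- matrix(0, k, 3)
  centers[1, ] <- x[sample.int(n, 1, prob = w), ]
  if (k > 1) for (j in 2:k) {
    d2 <- rowMins_mat(outer_dist(x, centers[1:(j - 1), , drop = FALSE])^2)
    p <- w * d2
    centers[j, ] <- if (sum(p) > 0) x[sample.int(n, 1, prob = p), ]
      else x[sample.int(n, 1, prob = w), ]
  }
  asg_old <- rep(0L, n)
  for (it in seq_len(iter_max)) {
    d2 <- outer_dist(x, centers)^2
    asg <- max.col(-d2, ties.method = "first")
    if (all(asg == asg_old)) break
    asg_old <- asg
    for (j in seq_len(k)) {
      m <- asg == j
      if (any(m)) centers[j, ] <- colSums(x[m, , drop = FALSE] * w[m]) / sum(w[m])
      else centers[j, ] <- x[which.max(w * rowMins_mat(d2)), ]
    }
  }
  d2 <- outer_dist(x, centers)^2
  asg <- max.col(-d2, ties.method = "first")
  list(centers = centers,
       mass = vapply(seq_len(k), function(j) sum(w[asg == j]), 0),
       distortion = sum(w * d2[cbind(seq_len(n), asg)]))
}

outer_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

rowMins_mat <- function(m) do.call(pmin, as.data.frame(m))

# Exact linear assignment (square cost matrix) by the Jonker-Volgenant
# shortest-augmenting-path algorithm, O(n^3). Returns, for each row, the
# assigned column of a minimum-cost perfect matching.
lap_solve <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)        # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF
      j1 <- 0L
      for (j in 2:(n + 1)) {
        if (used[j]) next
        cur <- cost[i0, j - 1] - u[i0 + 0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  asg <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) asg[p[j]] <- j - 1L
  asg
}

#' Level-of-detail estimate for feature points
#'
#' Divides the structure volume by the volume of one resolution element,
#' `r_s^3`, giving an upper bound on the number of resolvable features;
#' practical use brackets the count between 30% and 50% of that bound to
#' avoid overfitting.
#'
#' @param structure_volume molecular volume in cubic Angstrom.
#' @param r_s target-map Situs resolution in Angstrom.
#' @param level fraction of the upper bound, conventionally 0.3--0.5
#'   (1.0 gives the bound itself).
#' @return Integer `N >= 1`.
#' @export
estimate_n <- function(structure_volume, r_s, level = 0.4) {
  if (structure_volume <= 0 || r_s <= 0) stop("inputs must be positive")
  max(1L, as.integer(round(level * structure_volume / r_s^3)))
}

#' Target point count from the occupied-volume fraction
#'
#' When a smaller structure is docked into a larger (for example
#' oligomeric) density, `units` estimates how many copies of the structure
#' fill the target volume (it may be non-integer); the target cloud size is
#' `M = round(units * N)`.
#'
#' @param n probe feature count `N`.
#' @param units occupied-volume fraction (>= 1).
#' @return Integer `M`.
#' @export
units_to_m <- function(n, units) {
  if (units < 1) stop("units must be >= 1 (the target holds at least one copy)")
  as.integer(round(units * n))
}

#' Match a small feature-point cloud into a larger one (matchpt)
#'
#' Finds an injective correspondence of the `N` probe points to `M >= N`
#' target points together with the rigid transform superposing them,
#' ranked by RMSD. The heuristic seeds candidate matches from
#' anchor-triangle pairs -- probe point triples matched against target
#' triples with compatible pairwise distances (within `dist_tol`) -- fits
#' the rigid transform by least squares, extends the correspondence to the
#' remaining points (nearest unused target point; when two or fewer points
#' remain, all injective completions are enumerated), and re-fits. An
#' exact brute-force search over all injections is available for small
#' instances and is the reference the heuristic is validated against.
#'
#' @param probe,target [point_cloud]s (or n x 3 matrices); the probe must
#'   not be larger than the target and needs at least 3 points.
#' @param dist_tol anchor-triangle edge-compatibility tolerance in
#'   Angstrom; default 1.5 times the mean nearest-neighbor spacing of the
#'   target cloud.
#' @param method `"heuristic"`, `"exhaustive"`, or `"auto"` (exhaustive
#'   when `M <= 7`).
#' @param max_results number of ranked matches to return.
#' @param max_seed_triples cap on probe seed triangles (heuristic breadth).
#' @param max_target_seeds per probe triangle, cap on compatible target
#'   triangles explored (kept in order of edge-length mismatch).
#' @return List of `match_result`s, each with `correspondence` (target
#'   index per probe point), `R`, `t` (the transform, applied as
#'   `x %*% t(R) + t`), and `rmsd`; sorted by increasing RMSD.
#' @export
matchpt <- function(probe, target, dist_tol = NULL,
                    method = c("auto", "heuristic", "exhaustive"),
                    max_results = 10, max_seed_triples = 60,
                    max_target_seeds = 200) {
  method <- match.arg(method)
  P <- if (inherits(probe, "point_cloud")) probe$points else as.matrix(probe)
  T_ <- if (inherits(target, "point_cloud")) target$points else as.matrix(target)
  N <- nrow(P); M <- nrow(T_)
  if (N > M) stop("probe cloud (", N, ") is larger than target cloud (", M, ")")
  if (N < 3) stop("at least 3 probe points are needed for a rigid transform")
  if (method == "auto") method <- if (M <= 7) "exhaustive" else "heuristic"
  if (is.null(dist_tol)) {
    nnd <- apply(outer_dist(T_, T_) + diag(Inf, M), 1, min)
    dist_tol <- 1.5 * mean(nnd)
  }
  cands <- if (method == "exhaustive") match_exhaustive(P, T_)
    else match_heuristic(P, T_, dist_tol, max_seed_triples, max_target_seeds)
  if (length(cands) == 0)
    stop("no anchor triangle within the distance tolerance (",
         signif(dist_tol, 4), " A); increase dist_tol")
  key <- vapply(cands, function(m) paste(m$correspondence, collapse = ","), "")
  cands <- cands[!duplicated(key)]
  ord <- order(vapply(cands, `[[`, 0, "rmsd"))
  cands <- cands[ord[seq_len(min(max_results, length(ord)))]]
  lapply(cands, function(m) structure(m, class = "match_result"))
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: %d pairs, rmsd %.4g A\n",
              length(x$correspondence), x$rmsd))
  invisible(x)
}

fit_pairs <- function(P, T_, corr) {
  k <- kabsch(P, T_[corr, , drop = FALSE])
  list(correspondence = corr, R = k$R, t = k$t, rmsd = k$rmsd)
}

match_exhaustive <- function(P, T_) {
  N <- nrow(P); M <- nrow(T_)
  subs <- utils::combn(M, N, simplify = FALSE)
  out <- list()
  for (s in subs) {
    perms <- permutations_of(s)
    for (corr in perms) out[[length(out) + 1]] <- fit_pairs(P, T_, corr)
  }
  out
}

permutations_of <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in permutations_of(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

match_heuristic <- function(P, T_, dist_tol, max_seed_triples,
                            max_target_seeds = 200) {
  N <- nrow(P); M <- nrow(T_)
  dP <- outer_dist(P, P)
  dT <- outer_dist(T_, T_)
  triples <- utils::combn(N, 3, simplify = FALSE)
  if (length(triples) > max_seed_triples)
    triples <- triples[seq_len(max_seed_triples)]
  # all ordered target triples as one matrix, with their edge lengths,
  # so triangle compatibility is one vectorized comparison per probe triple
  tt <- utils::combn(M, 3)
  perm6 <- matrix(c(1, 2, 3, 1, 3, 2, 2, 1, 3, 2, 3, 1, 3, 1, 2, 3, 2, 1),
                  nrow = 3)
  ordered <- matrix(0L, nrow = 6 * ncol(tt), ncol = 3)
  for (p in 1:6)
    ordered[seq(p, by = 6, length.out = ncol(tt)), ] <- t(tt[perm6[, p], ,
                                                             drop = FALSE])
  te <- cbind(dT[ordered[, 1:2]], dT[ordered[, c(1, 3)]],
              dT[ordered[, 2:3]])
  seen <- new.env(hash = TRUE, parent = emptyenv())
  corrs <- list()
  for (pt in triples) {
    pe <- c(dP[pt[1], pt[2]], dP[pt[1], pt[3]], dP[pt[2], pt[3]])
    mis <- pmax(abs(te[, 1] - pe[1]),
                pmax(abs(te[, 2] - pe[2]), abs(te[, 3] - pe[3])))
    rows <- which(mis <= dist_tol)
    if (length(rows) > max_target_seeds)
      rows <- rows[order(mis[rows])][seq_len(max_target_seeds)]
    for (row in rows) {
      perm <- ordered[row, ]
      k3 <- kabsch(P[pt, , drop = FALSE], T_[perm, , drop = FALSE])
      corr <- extend_correspondence(P, T_, pt, perm, k3)
      if (is.null(corr)) next
      key <- paste(corr, collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      corrs[[length(corrs) + 1]] <- corr
    }
  }
  lapply(corrs, function(corr) fit_pairs(P, T_, corr))
}

# Complete a 3-pair seed to a full injective correspondence: predict each
# remaining probe point under the seed transform and take the nearest
# unused target point; when <= 2 points remain, enumerate all completions
# and keep the best by final RMSD.
extend_correspondence <- function(P, T_, pt, perm, k3) {
  N <- nrow(P); M <- nrow(T_)
  enumerate_tail <- if (M <= 8) 2L else 0L
  corr <- integer(N)
  corr[pt] <- perm
  remaining <- setdiff(seq_len(N), pt)
  used <- perm
  pred <- sweep(P %*% t(k3$R), 2, k3$t, "+")
  if (length(remaining) > enumerate_tail) {
    D <- outer_dist(pred[remaining, , drop = FALSE], T_)
    D[, used] <- Inf
    rows_left <- rep(TRUE, length(remaining))
    while (sum(rows_left) > enumerate_tail) {
      bi <- arrayInd(which.min(D), dim(D))
      i <- bi[1]; j <- bi[2]
      corr[remaining[i]] <- j
      used <- c(used, j)
      rows_left[i] <- FALSE
      D[i, ] <- Inf
      D[, j] <- Inf
    }
    remaining <- remaining[rows_left]
  }
  if (length(remaining) > 0) {
    avail <- setdiff(seq_len(M), used)
    combos <- if (length(remaining) == 1) lapply(avail, function(a) a)
      else {
        prs <- expand.grid(a = avail, b = avail)
        prs <- prs[prs$a != prs$b, ]
        lapply(seq_len(nrow(prs)), function(i) c(prs$a[i], prs$b[i]))
      }
    best <- NULL; best_rmsd <- Inf
    for (cmb in combos) {
      cc2 <- corr
      cc2[remaining] <- cmb
      f <- fit_pairs(P, T_, cc2)
      if (f$rmsd < best_rmsd) { best_rmsd <- f$rmsd; best <- cc2 }
    }
    corr <- best
  }
  corr
}

#' Quality report for a point-cloud match
#'
#' Combines the three selection criteria for a docking solution: the RMSD
#' of the matched feature points, the summed average variability of both
#' clouds (low variability indicates reproducible, trustworthy features),
#' and the cross-correlation of the posed atomic model against the target
#' map. Fields whose inputs are missing are reported as `NA`.
#'
#' @param result a `match_result` from [matchpt()].
#' @param probe_cloud,target_cloud the matched [point_cloud]s (for
#'   variability).
#' @param target_map optional [volume_map] for the CC term.
#' @param probe_model optional [atomic_model] posed by the match transform
#'   and rasterized for the CC term.
#' @param res Situs resolution for rasterization (defaults to 3 times the
#'   map width).
#' @return List with `rmsd`, `variability_sum`, `cc`.
#' @export
match_quality <- function(result, probe_cloud = NULL, target_cloud = NULL,
                          target_map = NULL, probe_model = NULL, res = NULL) {
  vsum <- NA_real_
  if (!is.null(probe_cloud) && !is.null(target_cloud) &&
      !is.null(probe_cloud$variability) && !is.null(target_cloud$variability))
    vsum <- mean(probe_cloud$variability) + mean(target_cloud$variability)
  ccv <- NA_real_
  if (!is.null(target_map) && !is.null(probe_model)) {
    if (is.null(res)) res <- 3 * target_map$width
    posed <- probe_model
    xyz <- sweep(coords(probe_model) %*% t(result$R), 2, result$t, "+")
    posed$x <- xyz[, 1]; posed$y <- xyz[, 2]; posed$z <- xyz[, 3]
    pm <- pdb2vol(posed, width = target_map$width,
                  kernel = gaussian_kernel(resolution = res),
                  lattice = list(origin = target_map$origin,
                                 dims = target_map$dims))
    ccv <- cc(target_map, pm)
  }
  list(rmsd = result$rmsd, variability_sum = vsum, cc = ccv)
}
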