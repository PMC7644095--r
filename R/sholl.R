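# Cone-restricted Sholl analysis: ring crossings of a rooted 2-D arbor and
# the defasciculation index (DI).
#
# Fifteen concentric circles 10 um apart are centred on the root (the point
# where the dorsal ramification opens). Every transversal crossing of a
# polyline segment with a circle is one intersection; a cone of full apex
# angle 15 deg is rotated about the root to capture as many crossings as
# possible, and DI = crossings outside that best cone / total crossings.
# Tightly fasciculated projections put every crossing in the cone (DI = 0);
# spread-out projections cannot be covered and DI grows toward 1.

#' Read a neurite skeleton
#'
#' Two dialects: standard 7-column SWC (`id type x y z radius parent`; z is
#' dropped — maximum-intensity-projection tracing convention) and a CSV
#' polyline dialect with header `branch_id,x_um,y_um` (the root is taken
#' from the `root` argument or a leading `# root: x y` comment). SWC
#' polylines are reconstructed between critical nodes (root, branch points,
#' tips), so a branch point is shared by the polylines it joins.
#'
#' @param path file to read.
#' @param dialect `"swc"` or `"csv_polyline"`.
#' @param root optional numeric `c(x, y)` ramification-opening point; for
#'   SWC the root node's coordinates are the default.
#' @param reject3d error on SWC files with nonzero z instead of projecting.
#' @return A [Skeleton-class].
#' @export
readSkeleton <- function(path, dialect = c("swc", "csv_polyline"),
                         root = NULL, reject3d = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (dialect == "swc") {
    tab <- utils::read.table(path, comment.char = "#",
                             col.names = c("id", "type", "x", "y", "z",
                                           "radius", "parent"))
    if (!nrow(tab)) stop("no nodes in ", path)
    if (reject3d && any(tab$z != 0))
      stop("SWC file has nonzero z coordinates")
    ids <- tab$id
    if (anyDuplicated(ids)) stop("duplicate SWC node ids")
    parent <- tab$parent
    rootIdx <- which(parent == -1L)
    if (length(rootIdx) != 1L)
      stop("SWC file must have exactly one root node (parent -1)")
    pidx <- match(parent, ids)
    orphan <- which(is.na(pidx) & parent != -1L)
    if (length(orphan))
      stop(sprintf("orphan parent reference %d at node id %d",
                   parent[orphan[1]], ids[orphan[1]]))
    nChildren <- tabulate(pidx[!is.na(pidx)], nbins = nrow(tab))
    critical <- nChildren > 1L
    critical[rootIdx] <- TRUE
    childrenOf <- split(seq_len(nrow(tab))[!is.na(pidx)],
                        pidx[!is.na(pidx)])
    branches <- list()
    for (k in which(critical | nChildren == 0L)) {
      if (!critical[k]) next
      for (child in childrenOf[[as.character(k)]]) {
        pathIdx <- c(k, child)
        cur <- child
        while (!critical[cur] && nChildren[cur] == 1L) {
          cur <- childrenOf[[as.character(cur)]][1]
          pathIdx <- c(pathIdx, cur)
        }
        branches[[length(branches) + 1L]] <-
          cbind(tab$x[pathIdx], tab$y[pathIdx])
      }
    }
    if (!length(branches)) stop("SWC file has fewer than 2 points per branch")
    if (is.null(root)) root <- c(tab$x[rootIdx], tab$y[rootIdx])
  } else {
    lines <- readLines(path)
    rootLine <- grep("^#\\s*root:", lines, value = TRUE)
    if (is.null(root)) {
      if (!length(rootLine))
        stop("csv_polyline dialect needs a root (argument or '# root: x y' comment)")
      root <- as.numeric(strsplit(trimws(
        sub("^#\\s*root:", "", rootLine[1])), "\\s+")[[1]])
    }
    body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
    if (length(body) < 2L) stop("no polyline rows in ", path)
    header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
    if (!identical(trimws(header), c("branch_id", "x_um", "y_um")))
      stop("csv_polyline dialect requires header 'branch_id,x_um,y_um'")
    f <- strsplit(body[-1], ",", fixed = TRUE)
    if (any(lengths(f) != 3L)) stop("malformed csv_polyline row")
    m <- t(vapply(f, identity, character(3)))
    xy <- matrix(as.numeric(m[, 2:3]), ncol = 2L)
    if (anyNA(xy)) stop("non-numeric coordinate in ", path)
    branches <- unname(lapply(split(seq_len(nrow(xy)), m[, 1]),
                              function(i) xy[i, , drop = FALSE]))
    short <- which(vapply(branches, nrow, 1L) < 2L)
    if (length(short)) stop("branch with fewer than 2 points")
  }
  skeleton(root = root, branches = branches)
}

#' Write a neurite skeleton
#'
#' Inverse of [readSkeleton()]. The CSV dialect stores the root in a
#' `# root: x y` comment and round-trips coordinates exactly. The SWC
#' dialect writes node 1 at the root and links each branch to it when the
#' branch starts at the root point.
#'
#' @param skel a [Skeleton-class].
#' @param path output file.
#' @param dialect `"swc"` or `"csv_polyline"`.
#' @export
writeSkeleton <- function(skel, path, dialect = c("swc", "csv_polyline")) {
  dialect <- match.arg(dialect)
  stopifnot(is(skel, "Skeleton"))
  validObject(skel)
  num <- function(x) sprintf("%.17g", x)
  if (dialect == "csv_polyline") {
    rows <- unlist(lapply(seq_along(skel@branches), function(i) {
      b <- skel@branches[[i]]
      sprintf("b%03d,%s,%s", i, num(b[, 1]), num(b[, 2]))
    }))
    writeLines(c(sprintf("# root: %s %s", num(skel@root[1]),
                         num(skel@root[2])),
                 "branch_id,x_um,y_um", rows), path)
  } else {
    lines <- sprintf("1 1 %s %s 0 1 -1", num(skel@root[1]),
                     num(skel@root[2]))
    nid <- 1L
    for (b in skel@branches) {
      atRoot <- isTRUE(all.equal(b[1, ], skel@root, tolerance = 0,
                                 check.attributes = FALSE))
      pts <- if (atRoot) b[-1, , drop = FALSE] else b
      parent <- if (atRoot) 1L else NA_integer_
      for (j in seq_len(nrow(pts))) {
        nid <- nid + 1L
        if (j == 1L && is.na(parent)) {
          # branch not anchored at the root: emit its first point as an
          # unconnected chain start linked to a duplicate anchor under root
          lines <- c(lines, sprintf("%d 0 %s %s 0 1 1", nid,
                                    num(b[1, 1]), num(b[1, 2])))
          prev <- nid
          next
        }
        p <- if (j == 1L) parent else prev
        lines <- c(lines, sprintf("%d 0 %s %s 0 1 %d", nid,
                                  num(pts[j, 1]), num(pts[j, 2]), p))
        prev <- nid
      }
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Ring crossings of a skeleton
#'
#' For each ring radius `r = k * ringSpacingUm` (`k = 1..nRings`) and each
#' polyline segment, every transversal crossing of the circle
#' `|p - root| = r` yields one crossing with its exact point and polar
#' angle. Tangential touches count once, and a crossing at a vertex shared
#' by two consecutive segments is deduplicated (geometric tolerance
#' `tolUm`). A skeleton with no crossings yields an empty set.
#'
#' @param skel a [Skeleton-class].
#' @param config a [ShollConfig-class].
#' @return `data.frame` with `ring` (1-based index), `angle_deg` (polar
#'   angle about the root in `[0, 360)`), `x`, `y`.
#' @export
ringIntersections <- function(skel, config = shollConfig()) {
  stopifnot(is(skel, "Skeleton"), is(config, "ShollConfig"))
  validObject(skel); validObject(config)
  radii <- seq_len(config@nRings) * config@ringSpacingUm
  tol <- config@tolUm
  out <- vector("list", length(skel@branches))
  for (bi in seq_along(skel@branches)) {
    b <- sweep(skel@branches[[bi]], 2L, skel@root)  # root at origin
    n <- nrow(b) - 1L
    hits <- list()
    for (si in seq_len(n)) {
      a <- b[si, ]; d <- b[si + 1L, ] - a
      A <- sum(d * d); B <- 2 * sum(a * d); C0 <- sum(a * a)
      # radial range of the segment: only rings it can reach
      tFoot <- -B / (2 * A)
      dEnds <- sqrt(c(C0, C0 + B + A))
      dMin <- if (tFoot > 0 && tFoot < 1)
        sqrt(max(0, C0 - B * B / (4 * A))) else min(dEnds)
      dMax <- max(dEnds)
      for (ri in which(radii >= dMin - tol & radii <= dMax + tol)) {
        C <- C0 - radii[ri]^2
        disc <- B * B - 4 * A * C
        eps <- tol * max(1, A, abs(C))
        if (disc < -eps) next
        ts <- if (disc <= eps) -B / (2 * A)
              else (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
        tEdge <- tol / sqrt(A)  # tolerance in t units
        for (t in ts) {
          if (t < -tEdge || t > 1 + tEdge) next
          p <- a + min(max(t, 0), 1) * d
          hits[[length(hits) + 1L]] <- c(ri, p)
        }
      }
    }
    if (!length(hits)) next
    h <- do.call(rbind, hits)
    # dedupe same-ring crossings closer than tol (shared vertices,
    # tangent re-hits from adjacent segments)
    keep <- rep(TRUE, nrow(h))
    ord <- order(h[, 1])
    h <- h[ord, , drop = FALSE]
    for (i in seq_len(nrow(h))[-1]) {
      j <- i - 1L
      while (j >= 1L && h[j, 1] == h[i, 1]) {
        if (keep[j] && sqrt(sum((h[i, 2:3] - h[j, 2:3])^2)) <= 10 * tol) {
          keep[i] <- FALSE
          break
        }
        j <- j - 1L
      }
    }
    out[[bi]] <- h[keep, , drop = FALSE]
  }
  h <- do.call(rbind, out)
  if (is.null(h) || !nrow(h))
    return(data.frame(ring = integer(), angle_deg = numeric(),
                      x = numeric(), y = numeric()))
  ang <- atan2(h[, 3], h[, 2]) * 180 / pi
  ang <- ang %% 360
  data.frame(ring = as.integer(h[, 1]), angle_deg = ang,
             x = h[, 2] + skel@root[1], y = h[, 3] + skel@root[2])
}

#' Best cone orientation
#'
#' Finds a cone center angle maximizing the number of crossing angles
#' within `center +/- coneFullAngleDeg / 2` (circular arithmetic). The
#' optimum is exact: an optimal cone can always be rotated until one edge
#' touches a crossing angle, so candidates with either edge anchored at
#' each crossing are exhaustive. The winning cone is re-centred on the
#' midpoint of the arc of angles it captures (so a single-angle crossing
#' set reports that angle); remaining ties are broken by the smallest
#' center angle in `[0, 360)`. Tie handling affects only the reported
#' orientation, never the count or the DI.
#'
#' @param crossings `data.frame` from [ringIntersections()] (or anything
#'   with an `angle_deg` column); must be nonempty.
#' @param config a [ShollConfig-class].
#' @return list with `coneCenterDeg` and `inCone`.
#' @export
bestCone <- function(crossings, config = shollConfig()) {
  stopifnot(is(config, "ShollConfig"))
  ang <- crossings$angle_deg
  if (!length(ang))
    stop("DI undefined: no intersections")
  half <- config@coneFullAngleDeg / 2
  angTol <- 1e-9
  centers <- sort(unique(c(ang + half, ang - half) %% 360))
  counts <- vapply(centers, function(ctr)
    sum(abs((ang - ctr + 180) %% 360 - 180) <= half + angTol), 1L)
  best <- max(counts)
  # re-centre each winning cone on the midpoint of its captured arc,
  # then take the smallest resulting center angle
  recentred <- vapply(centers[counts == best], function(ctr) {
    delta <- (ang - ctr + 180) %% 360 - 180
    delta <- delta[abs(delta) <= half + angTol]
    (ctr + (max(delta) + min(delta)) / 2) %% 360
  }, numeric(1))
  list(coneCenterDeg = min(recentred), inCone = as.integer(best))
}

#' Defasciculation index
#'
#' Composes [ringIntersections()] and [bestCone()]:
#' `di = (total - inCone) / total`, the fraction of ring crossings outside
#' the best-oriented cone. A skeleton crossing no ring has no defined DI
#' and raises an error (never 0).
#'
#' @param skel a [Skeleton-class].
#' @param config a [ShollConfig-class].
#' @return A [DIResult-class].
#' @examples
#' ray <- skeleton(c(0, 0), list(cbind(c(0, 0), c(0, 160))))
#' defasciculationIndex(ray)  # DI = 0: every crossing in the cone
#' @export
defasciculationIndex <- function(skel, config = shollConfig()) {
  cr <- ringIntersections(skel, config)
  if (!nrow(cr)) stop("DI undefined: no intersections")
  bc <- bestCone(cr, config)
  total <- nrow(cr)
  new("DIResult", total = as.integer(total), inCone = bc$inCone,
      di = (total - bc$inCone) / total,
      coneCenterDeg = bc$coneCenterDeg)
}

#' Batch DI over labeled skeletons
#'
#' Maps [defasciculationIndex()] over a list of skeletons (hemispheres).
#' Per-skeleton failures (e.g. no ring crossings) are flagged in their row
#' and the batch continues.
#'
#' @param skeletons named list of [Skeleton-class].
#' @param config a [ShollConfig-class].
#' @param groups optional group label per skeleton (recycled if length 1).
#' @return list with `rows` (per-skeleton `data.frame`: `label`, `group`,
#'   `total`, `in_cone`, `di`, `cone_center_deg`, `flag`) and `summary`
#'   (per-group `n`, `mean_di`, `sem_di`).
#' @export
diBatch <- function(skeletons, config = shollConfig(), groups = "all") {
  if (!length(skeletons)) stop("empty skeleton list")
  labels <- names(skeletons)
  if (is.null(labels)) labels <- sprintf("skel%03d", seq_along(skeletons))
  groups <- rep_len(groups, length(skeletons))
  rows <- lapply(seq_along(skeletons), function(i) {
    r <- tryCatch(defasciculationIndex(skeletons[[i]], config),
                  error = function(e) e)
    if (is(r, "error"))
      data.frame(label = labels[i], group = groups[i], total = NA_integer_,
                 in_cone = NA_integer_, di = NA_real_,
                 cone_center_deg = NA_real_, flag = conditionMessage(r))
    else
      data.frame(label = labels[i], group = groups[i], total = r@total,
                 in_cone = r@inCone, di = r@di,
                 cone_center_deg = r@coneCenterDeg, flag = "")
  })
  rows <- do.call(rbind, rows)
  ok <- !is.na(rows$di)
  summ <- do.call(rbind, lapply(split(rows$di[ok], rows$group[ok]),
    function(v) data.frame(n = length(v), mean_di = mean(v),
                           sem_di = stats::sd(v) / sqrt(length(v)))))
  if (!is.null(summ)) summ <- cbind(group = rownames(summ), summ,
                                    row.names = NULL)
  list(rows = rows, summary = summ)
}
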