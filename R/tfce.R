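## Threshold-free cluster enhancement over arbitrary neighborhood graphs
## (1-D sub-ROI curves with chain adjacency, or 3-D voxel lattices), with
## sign-flip permutation nulls and max-statistic FWER correction.

#' TFCE parameters
#'
#' @param extent_exponent,height_exponent TFCE exponents E and H (>= 0);
#'   defaults are the canonical 0.5 and 2.
#' @param dh Threshold step in statistic units; `NULL` uses
#'   `max(stat) / 100` per map.
#' @param n_permutations Sign-flip permutations (>= 100).
#' @param seed Integer seed.
#' @param tail `"one_sided_positive"` or `"two_sided"` (negative values
#'   enhanced separately and subtracted).
#' @return List of class `tfce_params`.
#' @export
tfce_params <- function(extent_exponent = 0.5, height_exponent = 2,
                        dh = NULL, n_permutations = 10000, seed = 1L,
                        tail = c("two_sided", "one_sided_positive")) {
  tail <- match.arg(tail)
  if (extent_exponent < 0 || height_exponent < 0) {
    stopf("TFCE exponents must be >= 0")
  }
  if (!is.null(dh) && dh <= 0) stopf("dh must be > 0")
  if (!is_count(n_permutations, 100L)) {
    stopf("n_permutations must be an integer >= 100")
  }
  structure(list(extent_exponent = extent_exponent,
                 height_exponent = height_exponent, dh = dh,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), tail = tail),
            class = "tfce_params")
}

#' Chain adjacency over n ordered positions
#'
#' Neighborhood for 1-D maps (e.g. decoding curves over graded sub-ROI
#' sizes): position i is adjacent to i-1 and i+1.
#'
#' @param n Number of positions.
#' @return Adjacency object for [tfce()].
#' @export
chain_adjacency <- function(n) {
  stopifnot(is_count(n))
  structure(list(type = "chain", n = as.integer(n)), class = "adjacency")
}

#' Face-connected lattice adjacency for a 3-D volume
#'
#' 6-connectivity over voxels; with a logical `mask`, positions are the
#' in-mask voxels (in column-major order) and edges connect face-adjacent
#' in-mask pairs.
#'
#' @param dim Length-3 integer volume dimensions.
#' @param mask Optional logical array of that dimension.
#' @return Adjacency object for [tfce()]; carries `positions` (linear voxel
#'   indices) when a mask is given.
#' @export
lattice_adjacency <- function(dim, mask = NULL) {
  stopifnot(length(dim) == 3)
  dim <- as.integer(dim)
  if (is.null(mask)) mask <- array(TRUE, dim)
  stopifnot(all(dim(mask) == dim))
  lin <- array(seq_len(prod(dim)), dim)
  keep <- which(mask)
  pos_of <- integer(prod(dim))
  pos_of[keep] <- seq_along(keep)
  edges <- NULL
  coord <- arrayInd(keep, dim)
  for (ax in 1:3) {
    nb <- coord
    nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= dim[ax]
    from <- keep[ok]
    to <- lin[nb[ok, , drop = FALSE]]
    ok2 <- mask[to]
    edges <- rbind(edges, cbind(pos_of[from[ok2]], pos_of[to[ok2]]))
  }
  structure(list(type = "graph", n = length(keep),
                 edges = if (is.null(edges)) matrix(0L, 0, 2) else edges,
                 positions = keep, dim = dim),
            class = "adjacency")
}

## Connected-component labels over active positions. Chain adjacency uses a
## run-length fast path; general graphs use union-find over the edge list.
component_sizes_at <- function(active, adjacency) {
  n <- adjacency$n
  comp <- integer(n) # 0 = inactive
  if (adjacency$type == "chain") {
    r <- rle(active)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    id <- 0L
    for (j in seq_along(r$values)) {
      if (r$values[j]) {
        id <- id + 1L
        comp[starts[j]:ends[j]] <- id
      }
    }
    sizes <- r$lengths[r$values]
  } else {
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    e <- adjacency$edges
    use <- active[e[, 1]] & active[e[, 2]]
    for (k in which(use)) {
      a <- find(e[k, 1]); b <- find(e[k, 2])
      if (a != b) parent[a] <- b
    }
    roots <- vapply(which(active), find, 1L)
    comp[active] <- match(roots, unique(roots))
    sizes <- tabulate(comp[active])
  }
  list(comp = comp, sizes = sizes)
}

## Chain maps are short (a handful of sub-ROI sizes), so all 2^n
## supra-threshold patterns can be tabulated once: column `code + 1` holds
## the component size at each position for that active pattern. Cached per
## n; lets the permutation null vectorise over thresholds.
.tfce_cache <- new.env(parent = emptyenv())

chain_size_table <- function(n) {
  key <- as.character(n)
  if (!is.null(.tfce_cache[[key]])) return(.tfce_cache[[key]])
  tab <- matrix(0, n, 2^n)
  for (code in 0:(2^n - 1)) {
    active <- bitwAnd(code, 2^(seq_len(n) - 1)) > 0
    r <- rle(active)
    sizes <- rep(ifelse(r$values, r$lengths, 0), r$lengths)
    tab[, code + 1] <- sizes
  }
  .tfce_cache[[key]] <- tab
  tab
}

tfce_one_tail <- function(stat_map, adjacency, E, H, dh) {
  n <- length(stat_map)
  out <- numeric(n)
  top <- max(stat_map)
  if (top <= 0) return(out)
  if (is.null(dh)) dh <- top / 100
  hs <- seq(dh, top, by = dh)
  if (adjacency$type == "chain" && n <= 12) {
    tab <- chain_size_table(n)
    active <- outer(stat_map, hs, ">=") # n x thresholds
    codes <- as.integer(drop(2^(seq_len(n) - 1) %*% active))
    e <- tab[, codes + 1, drop = FALSE]
    return(drop((e^E * active) %*% (hs^H * dh)))
  }
  for (h in hs) {
    active <- stat_map >= h
    cc <- component_sizes_at(active, adjacency)
    out[active] <- out[active] +
      cc$sizes[cc$comp[active]]^E * h^H * dh
  }
  out
}

#' Threshold-free cluster enhancement
#'
#' For each position p, integrates `extent(h, p)^E * h^H` over thresholds
#' `h = dh, 2dh, ...` up to `stat(p)`, where `extent(h, p)` is the size of
#' the connected supra-threshold (`stat >= h`) component containing p.
#' Under a two-sided tail the negated map is enhanced separately and
#' subtracted, so sign is preserved.
#'
#' @param stat_map Numeric vector of statistic values over positions.
#' @param adjacency [chain_adjacency()] or [lattice_adjacency()] object.
#' @param params [tfce_params()].
#' @return Numeric vector of enhanced values (same length).
#' @export
tfce <- function(stat_map, adjacency, params = tfce_params()) {
  stopifnot(inherits(adjacency, "adjacency"), inherits(params, "tfce_params"))
  stat_map <- as.numeric(stat_map)
  if (length(stat_map) == 0) stopf("empty statistic map")
  if (length(stat_map) != adjacency$n) {
    stopf("map length (%d) does not match adjacency (%d)",
          length(stat_map), adjacency$n)
  }
  if (any(!is.finite(stat_map))) stopf("statistic map must be finite")
  E <- params$extent_exponent; H <- params$height_exponent
  pos <- tfce_one_tail(stat_map, adjacency, E, H, params$dh)
  if (params$tail == "one_sided_positive") return(pos)
  pos - tfce_one_tail(-stat_map, adjacency, E, H, params$dh)
}

## One-sample t map across participants (rows) per position (columns).
group_t_map <- function(data) {
  n <- nrow(data)
  m <- colMeans(data)
  v <- (colSums(data^2) - n * m^2) / (n - 1)
  m / sqrt(pmax(v, .Machine$double.eps) / n)
}

#' Sign-flip permutation null of the maximum TFCE statistic
#'
#' For each permutation, every participant's map is multiplied by an
#' independent random sign, the one-sample t map across participants is
#' recomputed, TFCE applied, and the spatial maximum recorded (maximum of
#' `|TFCE|` under a two-sided tail). Also returns the observed t and TFCE
#' maps.
#'
#' @param group_data Participant x position matrix.
#' @param adjacency Neighborhood for [tfce()].
#' @param params [tfce_params()]; `n_permutations` and `seed` control the
#'   null, `tail` the enhancement.
#' @return List: `null_max` (length `n_permutations`), `t_observed`,
#'   `tfce_observed`.
#' @export
signflip_null <- function(group_data, adjacency, params = tfce_params()) {
  group_data <- as.matrix(group_data)
  n <- nrow(group_data)
  if (n < 2) stopf("signflip_null needs >= 2 participants")
  t_obs <- group_t_map(group_data)
  tfce_obs <- tfce(t_obs, adjacency, params)
  null_max <- with_seed(params$seed, {
    vapply(seq_len(params$n_permutations), function(i) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      tm <- group_t_map(group_data * s)
      max(abs(tfce(tm, adjacency, params)))
    }, numeric(1))
  })
  list(null_max = null_max, t_observed = t_obs, tfce_observed = tfce_obs)
}

#' Max-statistic multiple-comparison correction
#'
#' `p(pos) = (#{null_max >= observed(pos)} + 1) / (n_perm + 1)`, with
#' `z = qnorm(1 - p)`: how extreme each observed TFCE value is relative to
#' the permutation distribution of the map-wise maximum, controlling the
#' family-wise error rate.
#'
#' @param observed_tfce Observed TFCE map (vector). Two-sided maps are
#'   compared on `|TFCE|`.
#' @param null_max Null distribution of the map maximum.
#' @return List with `p` and `z` vectors.
#' @export
maxstat_correct <- function(observed_tfce, null_max) {
  if (length(null_max) == 0) stopf("null distribution is empty")
  obs <- abs(as.numeric(observed_tfce))
  p <- (vapply(obs, function(o) sum(null_max >= o), 0) + 1) /
    (length(null_max) + 1)
  list(p = p, z = stats::qnorm(1 - p))
}
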