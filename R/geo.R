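#' Great-circle distance between collection sites
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean Earth
#' radius). Vectorized over both points.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84).
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stop("invalid coordinates: |lat| <= 90 and |lon| <= 180 required")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371008.8) / 1000
}

#' Pairwise geographic distance matrix for a sample table
#'
#' @param meta Data frame with columns `sample`, `lat`, `lon`.
#' @return Symmetric matrix of great-circle distances in km.
#' @export
geo_distance_matrix <- function(meta) {
  stopifnot(all(c("sample", "lat", "lon") %in% names(meta)))
  n <- nrow(meta)
  D <- matrix(0, n, n, dimnames = list(meta$sample, meta$sample))
  for (i in seq_len(max(n - 1L, 0L)))
    for (j in seq(i + 1L, n)) {
      D[i, j] <- D[j, i] <- haversine_km(meta$lat[i], meta$lon[i],
                                         meta$lat[j], meta$lon[j])
    }
  D
}

#' Mantel test of association between two distance matrices
#'
#' Pearson correlation between the upper-triangle entries of the two
#' matrices, with significance from joint row/column permutations of one
#' matrix. The test is one-sided for positive association:
#' `p = (1 + #permuted r >= observed r) / (1 + n_perm)`.
#'
#' @param d_gen,d_geo Symmetric distance matrices over the same samples
#'   (matching dimnames are enforced when present).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed for reproducible permutations.
#' @return List with `r`, `p`, `n_perm`, `seed`. `r` is NA (with p NA)
#'   when either matrix is constant off-diagonal.
#' @export
mantel_test <- function(d_gen, d_geo, n_perm = 999, seed = NULL) {
  stopifnot(is.matrix(d_gen), is.matrix(d_geo),
            all(dim(d_gen) == dim(d_geo)), n_perm >= 1)
  if (!is.null(dimnames(d_gen)) && !is.null(dimnames(d_geo))) {
    if (!setequal(rownames(d_gen), rownames(d_geo)))
      stop("distance matrices cover different samples")
    d_geo <- d_geo[rownames(d_gen), rownames(d_gen)]
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(d_gen)
  ut <- upper.tri(d_gen)
  x <- d_gen[ut]; y <- d_geo[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant distance matrix: Mantel r undefined")
    return(list(r = NA_real_, p = NA_real_, n_perm = n_perm, seed = seed))
  }
  r_obs <- stats::cor(x, y)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n)
    stats::cor(x, d_geo[idx, idx][ut])
  }, numeric(1))
  p <- (1 + sum(r_perm >= r_obs)) / (1 + n_perm)
  list(r = r_obs, p = p, n_perm = n_perm, seed = seed)
}
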