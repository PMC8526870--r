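# Region anchor directions on the unit dome (z >= 0). The layout is schematic:
# +x anterior, -x posterior, +y lateral, -y medial, +z dorsal.
.region_anchors <- local({
  a <- rbind(
    frontal       = c( 1.0,  0.1, 0.30),
    parietal      = c(-0.4,  0.2, 0.90),
    temporal      = c( 0.1,  0.9, 0.10),
    occipital     = c(-1.0,  0.1, 0.20),
    insula        = c( 0.3,  0.7, 0.40),
    cingulate     = c( 0.0, -0.9, 0.30),
    somatosensory = c( 0.2,  0.2, 0.95)
  )
  a / sqrt(rowSums(a^2))
})

# uniform sample on the unit upper hemisphere
.sample_dome <- function(n) {
  z <- runif(n, 0, 1)
  th <- runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(th), y = r * sin(th), z = z)
}

#' Generate an equal-sized spherical cortical parcellation
#'
#' Places `n_per_hemisphere` parcel seeds on a unit hemisphere by
#' farthest-point sampling (the seven region anchors are always retained, so
#' every region label is represented) and assigns each parcel the label of
#' its nearest region anchor. Farthest-point seeds approximate the centroids
#' of an equal-area Voronoi decomposition of the cortical sheet. The right
#' hemisphere mirrors the left in the x coordinate; parcel ids are 0-based
#' and contiguous (left `0..n-1`, right `n..2n-1`).
#'
#' @param n_per_hemisphere Number of parcels per hemisphere (default 143,
#'   giving 286 in total). Must be at least 7, one parcel per region.
#' @param seed Integer seed; identical seeds reproduce identical coordinates.
#' @return A tibble of class `parcel_set` with columns `parcel_id`,
#'   `hemisphere`, `region`, `x`, `y`, `z`.
#' @examples
#' parcels <- generate_parcellation(30, seed = 1)
#' dplyr::count(parcels, hemisphere, region)
#' @export
generate_parcellation <- function(n_per_hemisphere = 143L, seed = 1L) {
  n <- .assert_count(n_per_hemisphere, "n_per_hemisphere", min = 7L)
  seed <- .assert_count(seed, "seed")
  set.seed(seed)

  n_cand <- max(2000L, 30L * n)
  cand <- .sample_dome(n_cand)
  pts <- .region_anchors
  if (n > 7L) {
    # farthest-point sampling: grow the seed set by the candidate with the
    # largest distance to its nearest already-selected seed
    mind <- apply(cand, 1L, function(p) min(colSums((t(pts) - p)^2)))
    for (k in seq_len(n - 7L)) {
      i <- which.max(mind)
      pts <- rbind(pts, cand[i, ])
      d_new <- colSums((t(cand) - cand[i, ])^2)
      mind <- pmin(mind, d_new)
    }
  }
  pts <- unname(pts[seq_len(n), , drop = FALSE])
  nearest <- apply(pts %*% t(.region_anchors), 1L, which.max)
  region <- rownames(.region_anchors)[nearest]

  left <- tibble(
    parcel_id = 0:(n - 1L), hemisphere = "left", region = region,
    x = pts[, 1], y = pts[, 2], z = pts[, 3]
  )
  right <- left |>
    mutate(parcel_id = .data$parcel_id + n, hemisphere = "right",
           x = -.data$x)
  out <- bind_rows(left, right)
  class(out) <- c("parcel_set", class(out))
  out
}
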