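#' Construct a patch landscape
#'
#' A landscape is a tibble of habitat patches, one row per patch, with
#' columns `id` (unique integer label), `area_ha` (patch area in hectares),
#' `depth_cm` (mean water depth in centimeters), and `x_m`, `y_m` (planar
#' centroid coordinates in meters). An optional `group` column tags patches
#' with a region label (e.g. `"north"`, `"central"`, `"south"`) used by
#' region-targeted scenarios.
#'
#' Coordinates must be projected (meters), not longitude/latitude: the
#' dispersal-kernel rate `alpha` is per meter, and the systems this model
#' targets span well under a few kilometers, where projection error is
#' negligible.
#'
#' @param patches A data frame with columns `id`, `area_ha`, `depth_cm`,
#'   `x_m`, `y_m`, and optionally `group`.
#' @return A tibble of class `marsh_landscape`.
#' @examples
#' landscape(data.frame(id = 1:2, area_ha = c(1, 2), depth_cm = c(3, 4),
#'                      x_m = c(0, 100), y_m = c(0, 0)))
#' @export
landscape <- function(patches) {
  stopifnot(is.data.frame(patches))
  required <- c("id", "area_ha", "depth_cm", "x_m", "y_m")
  missing <- setdiff(required, names(patches))
  if (length(missing) > 0) {
    rlang::abort(paste0("landscape is missing column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "marshpva_bad_landscape")
  }
  keep <- intersect(c(required, "group"), names(patches))
  out <- tibble::as_tibble(patches[keep])
  if (anyDuplicated(out$id)) {
    rlang::abort("landscape column `id` contains duplicates",
                 class = "marshpva_bad_landscape")
  }
  for (col in c("area_ha", "depth_cm")) {
    v <- out[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0)) {
      rlang::abort(paste0("landscape column `", col,
                          "` must be numeric, non-missing and >= 0"),
                   class = "marshpva_bad_landscape")
    }
  }
  if (anyNA(out$x_m) || anyNA(out$y_m)) {
    rlang::abort("landscape coordinates `x_m`, `y_m` must be non-missing",
                 class = "marshpva_bad_landscape")
  }
  class(out) <- c("marsh_landscape", class(out))
  out
}

#' Read a landscape from CSV
#'
#' The CSV must have a header with columns `id,area_ha,depth_cm,x_m,y_m`
#' (and optionally `group`). Validation errors name the offending field.
#'
#' @param path Path to a landscape CSV file.
#' @return A `marsh_landscape` tibble.
#' @seealso [write_landscape()], [landscape()]
#' @export
read_landscape <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  landscape(df)
}

#' Write a landscape to CSV
#'
#' @param x A `marsh_landscape` (or compatible data frame).
#' @param path Output file path.
#' @return `x`, invisibly.
#' @export
write_landscape <- function(x, path) {
  x <- landscape(x)
  readr::write_csv(x, path)
  invisible(x)
}

#' Pairwise center-to-center distance matrix
#'
#' Euclidean distances in meters between patch centroids. Patches are
#' treated as points; patch radius plays no role in migration.
#'
#' @param x A `marsh_landscape`.
#' @return A symmetric n-by-n matrix with zero diagonal, rows and columns
#'   ordered as the patches of `x` and dimnames set to the patch ids.
#' @export
patch_distances <- function(x) {
  x <- landscape(x)
  d <- as.matrix(stats::dist(cbind(x$x_m, x$y_m)))
  dimnames(d) <- list(x$id, x$id)
  d
}

#' Per-patch carrying capacity
#'
#' Carrying capacity of each patch is `K_i = depth_cm * area_ha * k_volume`,
#' where `k_volume` is the habitat-volume density of the species at carrying
#' capacity, in voles per (cm x ha). A patch with zero water or zero area
#' has `K = 0` and supports no subpopulation.
#'
#' @param x A `marsh_landscape` (or any data frame with `area_ha` and
#'   `depth_cm` columns).
#' @param k_volume Voles supportable per unit habitat volume (cm x ha);
#'   must be >= 0. Default 17.
#' @return A numeric vector of carrying capacities, one per patch, named by
#'   patch id when an `id` column is present.
#' @examples
#' carrying_capacity(data.frame(id = 1, area_ha = 3, depth_cm = 2), 17) # 102
#' @export
carrying_capacity <- function(x, k_volume = 17) {
  stopifnot(is.data.frame(x), all(c("area_ha", "depth_cm") %in% names(x)))
  if (!is.numeric(k_volume) || length(k_volume) != 1 || is.na(k_volume) ||
      k_volume < 0) {
    rlang::abort("`k_volume` must be a single number >= 0",
                 class = "marshpva_bad_param")
  }
  if (any(x$area_ha < 0) || any(x$depth_cm < 0)) {
    rlang::abort("`area_ha` and `depth_cm` must be >= 0",
                 class = "marshpva_bad_param")
  }
  k <- x$depth_cm * x$area_ha * k_volume
  if (!is.null(x$id)) names(k) <- x$id
  k
}

#' Generate a synthetic marsh landscape
#'
#' Draws a reproducible synthetic landscape emulating a small desert wetland
#' complex: a few dozen marsh patches in regional clusters strung along a
#' few kilometers of valley floor, with within-cluster spacings of tens to
#' hundreds of meters and heterogeneous areas and water depths. The default
#' preset produces 36 patches in three clusters (north, central, south).
#' Areas are drawn log-uniformly and depths uniformly, so carrying
#' capacities at `k_volume = 17` are right-skewed and span roughly 1 to 130
#' individuals — most patches small, a handful large — matching the span
#' and skew of observed subpopulation sizes in well-studied marsh systems
#' of this kind. It is a fixture for simulation experiments, not a
#' reconstruction of any real geometry.
#'
#' @param n_patches Total number of patches; must equal the sum of cluster
#'   counts. Default 36.
#' @param clusters A data frame with one row per cluster and columns
#'   `name`, `n` (patch count), `x`, `y` (cluster center, m), and `spread`
#'   (standard deviation of patch displacement from the center, m).
#' @param area_range Range (ha) of log-uniform area draws.
#'   Default `c(0.02, 1.1)`.
#' @param depth_range Range (cm) of uniform depth draws. Default `c(2, 7)`.
#' @param seed Integer seed; the same seed always yields the same landscape.
#' @return A `marsh_landscape` tibble with a `group` column naming each
#'   patch's cluster.
#' @examples
#' land <- synthetic_landscape(seed = 1)
#' nrow(land)             # 36
#' range(carrying_capacity(land))
#' @export
synthetic_landscape <- function(n_patches = 36,
                                clusters = default_clusters(),
                                area_range = c(0.02, 1.1),
                                depth_range = c(2, 7),
                                seed = 1) {
  stopifnot(n_patches >= 1, is.data.frame(clusters),
            all(c("name", "n", "x", "y", "spread") %in% names(clusters)))
  if (any(area_range <= 0)) {
    rlang::abort("`area_range` must be positive (areas are drawn log-uniformly)",
                 class = "marshpva_bad_param")
  }
  if (any(depth_range < 0)) {
    rlang::abort("`depth_range` must be nonnegative",
                 class = "marshpva_bad_param")
  }
  if (sum(clusters$n) != n_patches) {
    rlang::abort("cluster counts must sum to `n_patches`",
                 class = "marshpva_bad_param")
  }
  withr_seed(seed, {
    rows <- purrr::pmap(clusters, function(name, n, x, y, spread) {
      tibble::tibble(
        group = name,
        x_m = stats::rnorm(n, x, spread),
        y_m = stats::rnorm(n, y, spread),
        area_ha = exp(stats::runif(n, log(area_range[1]),
                                   log(area_range[2]))),
        depth_cm = stats::runif(n, depth_range[1], depth_range[2])
      )
    })
    out <- dplyr::bind_rows(rows)
    out$id <- seq_len(nrow(out))
    landscape(out[c("id", "area_ha", "depth_cm", "x_m", "y_m", "group")])
  })
}

#' Default cluster layout for the synthetic landscape
#'
#' Three regional clusters (north, central, south) with centers roughly
#' 1.4 km apart along a valley-floor axis, so between-cluster dispersal is
#' rare, while within-cluster patches (spread 250 m, typical separations of
#' tens to a few hundred meters) exchange occasional migrants.
#'
#' @return A data frame of cluster specifications for
#'   [synthetic_landscape()].
#' @export
default_clusters <- function() {
  tibble::tibble(
    name = c("north", "central", "south"),
    n = c(10, 14, 12),
    x = c(300, 700, 1100),
    y = c(2600, 1300, 200),
    spread = c(250, 250, 250)
  )
}

# Evaluate an expression under a local, restored RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
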