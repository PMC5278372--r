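#' Configuration for the synthetic-landscape generator
#'
#' The generator stands in for real co-registered rasters: it produces
#' spatially autocorrelated categorical landscapes, factor surfaces
#' correlated with class placement, point/line feature masks for distance
#' factors, partial evidence rasters, and forward-simulated change under a
#' known transition model. One explicit seed fully determines all outputs.
#'
#' Default class proportions follow the reconstructed 1930s composition of
#' the Zhenlai case study (grassland-dominated farming-pastoral ecotone):
#' grassland 63.17%, arable 24.45%, wetland 9.69%, water 1.74%, settlement
#' 0.71%, forest 0.13%, other unused 0.12%.
#'
#' @param n_rows,n_cols Grid shape (default 200 x 200).
#' @param proportions Named class proportions summing to 1 over the schema
#'   classes.
#' @param smooth_radius Box-smoothing radius in cells (default 5);
#'   controls spatial autocorrelation.
#' @param n_point_features,n_line_features Feature counts per generated
#'   feature layer (default 12 points, 3 lines).
#' @param evidence_coverage Fraction of valid cells carried in the partial
#'   evidence raster (default 0.1).
#' @param factor_agreement Probability that a correlated categorical
#'   factor repeats its class's preferred category (default 0.7).
#' @param seed Integer seed.
#' @param schema An [lu_schema()].
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_rows = 200L, n_cols = 200L,
                         proportions = c(arable = 0.2445, forest = 0.0013,
                                         grassland = 0.6317, water = 0.0174,
                                         settlement = 0.0071,
                                         wetland = 0.0969,
                                         other_unused = 0.0011),
                         smooth_radius = 5L,
                         n_point_features = 12L, n_line_features = 3L,
                         evidence_coverage = 0.1, factor_agreement = 0.7,
                         seed = 1L, schema = schema_7class()) {
  if (!setequal(names(proportions), schema_names(schema)))
    stop("proportions must name every schema class")
  proportions <- proportions[schema_names(schema)]
  if (abs(sum(proportions) - 1) > 1e-6)
    stop(sprintf("proportions sum to %.4f, not 1", sum(proportions)))
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 proportions = proportions,
                 smooth_radius = as.integer(smooth_radius),
                 n_point_features = as.integer(n_point_features),
                 n_line_features = as.integer(n_line_features),
                 evidence_coverage = evidence_coverage,
                 factor_agreement = factor_agreement,
                 seed = as.integer(seed), schema = schema),
            class = "synth_config")
}

#' Generate a spatially autocorrelated categorical landscape
#'
#' One independent uniform-noise field per class is box-smoothed with the
#' configured radius; class extents are then carved by rank: classes are
#' visited in decreasing target share and each takes its largest-remainder
#' cell count from the highest-ranking still-unassigned cells of its own
#' field. Realised class counts therefore match the target proportions
#' exactly (up to integer rounding), and smoothing yields contiguous
#' patches.
#'
#' @param config A [synth_config()].
#' @return An [lu_grid()].
#' @export
generate_landscape <- function(config) {
  withr::with_seed(config$seed, {
    nr <- config$n_rows; nc <- config$n_cols
    sch <- config$schema
    k <- length(sch$codes)
    fields <- lapply(seq_len(k), function(i)
      box_smooth(matrix(stats::runif(nr * nc), nr, nc),
                 config$smooth_radius))
    counts <- largest_remainder(config$proportions, nr * nc)
    out <- matrix(NA_integer_, nr, nc)
    unassigned <- rep(TRUE, nr * nc)
    for (i in order(-config$proportions, seq_len(k))) {
      if (counts[i] == 0L) next
      idx <- which(unassigned)
      take <- idx[order(-fields[[i]][idx], idx)][seq_len(counts[i])]
      out[take] <- sch$codes[[i]]
      unassigned[take] <- FALSE
    }
    lu_grid(out, sch, lu_geometry(nr, nc))
  })
}

#' Generate factor, feature and evidence rasters for a landscape
#'
#' Produces (a) categorical factor grids correlated with the landscape:
#' each factor has one preferred category per class (a random permutation)
#' repeated with probability `factor_agreement`, otherwise a uniformly
#' random category; (b) point and line feature masks (settlement-like
#' points; river/road-like lines drawn between random border cells) for
#' distance factors; and (c) a partial evidence raster equal to the
#' landscape on a random subset of cells.
#'
#' @param landscape An [lu_grid()].
#' @param config A [synth_config()] (its `seed` offsets the landscape seed
#'   so factors differ from the fields that built the landscape).
#' @param factor_names Names of the categorical factors to generate.
#' @return A list: `factors` (named list of integer category matrices),
#'   `features` (named list of logical masks: `settlements`, `rivers`,
#'   `roads`), `evidence` (an `lu_grid` with `NA` where silent).
#' @export
generate_factors <- function(landscape, config,
                             factor_names = c("soil", "geomorphology",
                                              "elevation", "slope",
                                              "aspect")) {
  withr::with_seed(config$seed + 1000L, {
    v <- landscape$values
    nr <- nrow(v); nc <- ncol(v)
    k <- length(landscape$schema$codes)
    factors <- lapply(factor_names, function(fn) {
      pref <- sample.int(k)               # class -> preferred category
      cat_m <- matrix(sample.int(k, nr * nc, replace = TRUE), nr, nc)
      keep <- matrix(stats::runif(nr * nc) < config$factor_agreement, nr, nc)
      ok <- keep & !is.na(v)
      cat_m[ok] <- pref[match(v[ok], landscape$schema$codes)]
      cat_m[is.na(v)] <- NA_integer_
      cat_m
    })
    names(factors) <- factor_names
    valid_idx <- which(!is.na(v))
    pts <- function(n) {
      m <- matrix(FALSE, nr, nc)
      m[sample(valid_idx, min(n, length(valid_idx)))] <- TRUE
      m
    }
    lines <- function(n) {
      m <- matrix(FALSE, nr, nc)
      for (i in seq_len(n)) {
        p1 <- c(sample.int(nr, 1L), 1L)
        p2 <- c(sample.int(nr, 1L), nc)
        steps <- max(nr, nc) * 2L
        t <- seq(0, 1, length.out = steps)
        r <- pmin(pmax(round(p1[1L] + t * (p2[1L] - p1[1L])), 1L), nr)
        cc <- pmin(pmax(round(p1[2L] + t * (p2[2L] - p1[2L])), 1L), nc)
        m[cbind(r, cc)] <- TRUE
      }
      m
    }
    features <- list(settlements = pts(config$n_point_features),
                     rivers = lines(config$n_line_features),
                     roads = lines(config$n_line_features))
    evid <- matrix(NA_integer_, nr, nc)
    n_ev <- floor(config$evidence_coverage * length(valid_idx))
    if (n_ev > 0L) {
      pick <- sample(valid_idx, n_ev)
      evid[pick] <- v[pick]
    }
    list(factors = factors, features = features,
         evidence = lu_grid(evid, landscape$schema, landscape$geometry))
  })
}

#' Forward-simulate land-use change under a transition model
#'
#' Each cell of class i moves to class j with probability `p[i, j]`,
#' obtained by row-normalising the supplied transition matrix (areas,
#' counts or probabilities). With a suitability stack, per-cell
#' probabilities are additionally weighted by the destination's local
#' suitability (`p[i, j] * (1 + S_j(cell)/255)`, renormalised), which
#' clusters change but biases realised rates; matrix-recovery experiments
#' should omit it.
#'
#' @param map_t1 An [lu_grid()].
#' @param transition An `lu_transition` or plain matrix over the schema
#'   classes; every class present in `map_t1` needs a row with positive
#'   total.
#' @param suitability Optional named list of [factor_layer()]s.
#' @param seed Integer seed.
#' @return An `lu_grid` for time 2.
#' @export
simulate_forward_change <- function(map_t1, transition, suitability = NULL,
                                    seed = 1L) {
  sch <- map_t1$schema
  cls <- schema_names(sch)
  if (!setequal(rownames(transition), cls))
    stop("transition matrix classes do not match the map schema")
  P <- unclass(transition)[cls, cls]
  rs <- rowSums(P)
  present <- class_counts(map_t1) > 0L
  if (any(present & rs <= 0))
    stop("non-stochastic row(s) for present class(es): ",
         paste(cls[present & rs <= 0], collapse = ", "))
  P <- P / ifelse(rs > 0, rs, 1)
  v <- map_t1$values
  out <- v
  withr::with_seed(seed, {
    for (i in which(present)) {
      idx <- which(!is.na(v) & v == sch$codes[[i]])
      if (!length(idx)) next
      if (is.null(suitability)) {
        dest <- sample.int(length(cls), length(idx), replace = TRUE,
                           prob = P[i, ])
      } else {
        w <- vapply(cls, function(cl2)
          1 + suitability[[cl2]]$values[idx] / 255, numeric(length(idx)))
        pr <- sweep(w, 2L, P[i, ], `*`)
        pr <- pr / rowSums(pr)
        u <- stats::runif(length(idx))
        cum <- t(apply(pr, 1L, cumsum))
        dest <- max.col(cum >= u, ties.method = "first")
      }
      out[idx] <- sch$codes[dest]
    }
  })
  lu_grid(out, sch, map_t1$geometry)
}
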