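#' Pairwise Pearson correlation matrix for an ROI time series
#'
#' Computes all pairwise Pearson correlations between ROI columns. The
#' diagonal (self-correlations) is flagged as excluded and never enters any
#' downstream average.
#'
#' @param ts A numeric T x R matrix (rows = timepoints, columns = ROIs) with
#'   column names giving ROI identifiers, or a data frame of the same shape.
#' @return A `segspeech_connectivity` object: a list with elements `values`
#'   (R x R symmetric matrix, diagonal `NA`), `scale` (`"r"` or `"z"`), and
#'   `rectified` (logical).
#' @export
correlation_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (!is.numeric(ts)) {
    stop_segspeech("time series must be numeric", "segspeech_schema_error")
  }
  if (nrow(ts) < 3) {
    stop_segspeech("need at least 3 timepoints", "segspeech_schema_error")
  }
  if (any(!is.finite(ts))) {
    stop_segspeech("time series contains non-finite values", "segspeech_schema_error")
  }
  if (is.null(colnames(ts))) {
    colnames(ts) <- sprintf("roi%03d", seq_len(ncol(ts)))
  }
  sds <- apply(ts, 2, sd)
  if (any(sds == 0)) {
    stop_segspeech(
      sprintf(
        "zero-variance ROI column(s): %s",
        paste(colnames(ts)[sds == 0], collapse = ", ")
      ),
      "segspeech_degenerate_error"
    )
  }
  r <- cor(ts)
  diag(r) <- NA_real_
  new_connectivity(r, scale = "r", rectified = FALSE)
}

new_connectivity <- function(values, scale, rectified) {
  stopifnot(isSymmetric(unname(ifelse(is.na(values), 0, values)), tol = 1e-12))
  structure(
    list(values = values, scale = scale, rectified = rectified),
    class = "segspeech_connectivity"
  )
}

#' @export
print.segspeech_connectivity <- function(x, ...) {
  cat(sprintf(
    "<connectivity matrix: %d ROIs, scale = %s, rectified = %s>\n",
    nrow(x$values), x$scale, x$rectified
  ))
  invisible(x)
}

#' Fisher z-transform a correlation matrix
#'
#' Applies `atanh` elementwise off-diagonal to stabilize variance before
#' averaging. Correlations with `|r| >= 1 - 1e-7` (e.g., from duplicated
#' series) are clipped to that bound first so the transform stays finite.
#'
#' @param c A `segspeech_connectivity` object on the correlation scale.
#' @return The same object on the z scale.
#' @export
fisher_z <- function(c) {
  stopifnot(inherits(c, "segspeech_connectivity"))
  if (c$scale != "r") {
    stop_segspeech("matrix is already z-transformed", "segspeech_usage_error")
  }
  r <- c$values
  clip <- 1 - 1e-7
  r[!is.na(r) & r > clip] <- clip
  r[!is.na(r) & r < -clip] <- -clip
  z <- atanh(r)
  new_connectivity(z, scale = "z", rectified = c$rectified)
}

#' Zero out negative connectivity values
#'
#' Negative correlations are set to zero before averaging, reflecting
#' uncertainty about their physiological interpretation. Since `atanh(0) = 0`
#' and `atanh` is monotone odd, rectifying on the r or z scale is equivalent;
#' this implementation rectifies whatever scale it is given. Idempotent.
#'
#' @param c A `segspeech_connectivity` object.
#' @return The object with all negative off-diagonal entries replaced by 0
#'   and `rectified = TRUE`.
#' @export
rectify_negatives <- function(c) {
  stopifnot(inherits(c, "segspeech_connectivity"))
  v <- c$values
  v[!is.na(v) & v < 0] <- 0
  new_connectivity(v, scale = c$scale, rectified = TRUE)
}

check_rectified_z <- function(c) {
  stopifnot(inherits(c, "segspeech_connectivity"))
  if (c$scale != "z" || !c$rectified) {
    stop_segspeech(
      "connectivity matrix must be Fisher z-transformed and rectified",
      "segspeech_usage_error"
    )
  }
  invisible(c)
}

#' Mean within-network connectivity
#'
#' Mean of the z-transformed connectivity over all n(n-1)/2 unique ROI pairs
#' inside one network. The diagonal never enters the average.
#'
#' @param c A rectified, z-scale `segspeech_connectivity` object whose row
#'   and column names match atlas ROI identifiers.
#' @param atlas A `segspeech_atlas`.
#' @param network One of `"language"`, `"dmn"`, `"md"`.
#' @return Mean z value (scalar).
#' @export
within_network_fc <- function(c, atlas, network) {
  check_rectified_z(c)
  rois <- atlas_rois(atlas, network)
  if (length(rois) < 2) {
    stop_segspeech(
      sprintf("network '%s' has fewer than 2 ROIs", network),
      "segspeech_degenerate_error"
    )
  }
  sub <- c$values[rois, rois, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Mean between-network connectivity for a network pair
#'
#' Mean of the z-transformed connectivity over all |A| x |B| cross edges
#' between two distinct networks. Symmetric in argument order.
#'
#' @inheritParams within_network_fc
#' @param net_a,net_b Distinct network labels.
#' @return Mean z value (scalar).
#' @export
between_network_fc <- function(c, atlas, net_a, net_b) {
  check_rectified_z(c)
  if (identical(net_a, net_b)) {
    stop_segspeech("net_a and net_b must be distinct networks", "segspeech_usage_error")
  }
  a <- atlas_rois(atlas, net_a)
  b <- atlas_rois(atlas, net_b)
  mean(c$values[a, b, drop = FALSE])
}

#' Between-network connectivity (BNC) under the asymmetric definition
#'
#' The three networks are treated asymmetrically: the language network's BNC
#' is the unweighted mean of its two pair-means with DMN and MD, whereas the
#' DMN's and MD network's BNC is their reciprocal DMN-MD coupling (so
#' `network_bnc(c, atlas, "dmn") == network_bnc(c, atlas, "md")` for any
#' matrix). This keeps DMN/MD segregation interpretable as domain-general
#' differentiation, not differentiation from the specialized language system.
#'
#' @inheritParams within_network_fc
#' @param pooled If `TRUE`, the language BNC pools all cross edges into a
#'   single mean instead of averaging the two pair-means (sensitivity
#'   variant; default `FALSE`).
#' @return Mean z value (scalar).
#' @export
network_bnc <- function(c, atlas, network, pooled = FALSE) {
  check_rectified_z(c)
  if (network == "language") {
    if (pooled) {
      a <- atlas_rois(atlas, "language")
      b <- c(atlas_rois(atlas, "dmn"), atlas_rois(atlas, "md"))
      return(mean(c$values[a, b, drop = FALSE]))
    }
    return(mean(c(
      between_network_fc(c, atlas, "language", "dmn"),
      between_network_fc(c, atlas, "language", "md")
    )))
  }
  if (network %in% c("dmn", "md")) {
    return(between_network_fc(c, atlas, "dmn", "md"))
  }
  stop_segspeech(sprintf("unknown network label: %s", network), "segspeech_usage_error")
}

#' Network segregation
#'
#' Segregation = (within - between) / within. Values near 1 indicate a
#' network whose internal cohesion dwarfs its coupling to other systems;
#' 0 means within- and between-network connectivity are equal. After
#' rectification (between >= 0), segregation is at most 1 and equals 1 iff
#' the between-network connectivity is exactly 0.
#'
#' @param within Mean within-network z connectivity (> 0).
#' @param bnc Mean between-network z connectivity.
#' @return Unitless segregation value.
#' @export
segregation <- function(within, bnc) {
  if (!is.finite(within) || !is.finite(bnc)) {
    stop_segspeech("within and bnc must be finite", "segspeech_schema_error")
  }
  if (within <= 0) {
    stop_segspeech(
      sprintf("within-network connectivity must be positive (got %g)", within),
      "segspeech_degenerate_error"
    )
  }
  (within - bnc) / within
}

#' Per-network connectivity metrics for one participant
#'
#' Runs the full metric chain: Pearson correlations, Fisher z, negative
#' rectification, then within-network FC, asymmetric BNC, and segregation
#' for each of the three networks. Also returns the raw pairwise means used
#' by the supplementary within/between-connectivity models.
#'
#' @param ts A T x R numeric matrix with ROI identifiers as column names
#'   covering every atlas ROI.
#' @param atlas A `segspeech_atlas`.
#' @param pooled_language_bnc Passed to [network_bnc()] as `pooled`.
#' @return A tibble with one row per network and columns `network`,
#'   `within_fc`, `bnc`, `segregation`.
#' @export
#' @examples
#' atlas <- network_atlas()
#' ts <- simulate_timeseries(50, atlas, generator_params(), seed = 1)
#' compute_network_metrics(ts, atlas)
compute_network_metrics <- function(ts, atlas, pooled_language_bnc = FALSE) {
  missing <- setdiff(atlas$roi_id, colnames(ts))
  if (length(missing)) {
    stop_segspeech(
      sprintf("time series lacks ROI columns: %s", paste(missing, collapse = ", ")),
      "segspeech_schema_error"
    )
  }
  cm <- rectify_negatives(fisher_z(correlation_matrix(ts)))
  nets <- c("language", "dmn", "md")
  within <- vapply(nets, function(n) within_network_fc(cm, atlas, n), numeric(1))
  bnc <- vapply(
    nets, function(n) network_bnc(cm, atlas, n, pooled = pooled_language_bnc),
    numeric(1)
  )
  seg <- mapply(segregation, within, bnc)
  tibble::tibble(network = nets, within_fc = within, bnc = bnc, segregation = seg)
}
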