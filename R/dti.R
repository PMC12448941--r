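#' Eigenvalues of a diffusion tensor
#'
#' @param tensor symmetric 3x3 diffusion tensor (mm^2/s) or a length-3
#'   eigenvalue vector (returned sorted).
#' @param tol asymmetry tolerance relative to the largest element.
#'
#' @return Numeric vector `c(lambda1, lambda2, lambda3)`, descending.
#' @export
tensor_eigenvalues <- function(tensor, tol = 1e-8) {
  if (is.numeric(tensor) && length(tensor) == 3L)
    return(sort(tensor, decreasing = TRUE))
  if (!is.matrix(tensor) || !all(dim(tensor) == c(3L, 3L)))
    stop("`tensor` must be a 3x3 matrix or length-3 eigenvalues",
         call. = FALSE)
  asym <- max(abs(tensor - t(tensor)))
  if (asym > tol * max(1, max(abs(tensor))))
    stop("tensor is asymmetric beyond tolerance (max |T - T'| = ",
         format(asym, digits = 3), ")", call. = FALSE)
  ev <- eigen((tensor + t(tensor)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  sort(ev, decreasing = TRUE)
}

#' Fractional anisotropy of an eigenvalue triple
#'
#' The normalized eigenvalue-dispersion statistic of the diffusion tensor,
#' \deqn{FA = \sqrt{\tfrac{1}{2}}\,
#'   \frac{\sqrt{(\lambda_1-\lambda_2)^2 + (\lambda_2-\lambda_3)^2 +
#'        (\lambda_3-\lambda_1)^2}}
#'        {\sqrt{\lambda_1^2 + \lambda_2^2 + \lambda_3^2}},}
#' scaled between 0 (isotropic diffusion) and 1 (fully anisotropic,
#' degenerate diffusion along a single axis).
#'
#' @param lambda1,lambda2,lambda3 tensor eigenvalues (any common unit);
#'   alternatively pass a length-3 vector as `lambda1`. Vectorized over
#'   triples when given three equal-length vectors.
#'
#' @return FA in \[0, 1\].
#' @export
fractional_anisotropy <- function(lambda1, lambda2 = NULL, lambda3 = NULL) {
  if (is.null(lambda2) && length(lambda1) == 3L) {
    lambda3 <- lambda1[3]; lambda2 <- lambda1[2]; lambda1 <- lambda1[1]
  }
  l1 <- lambda1; l2 <- lambda2; l3 <- lambda3
  if (any(l1 < 0 | l2 < 0 | l3 < 0))
    stop("eigenvalues must be non-negative", call. = FALSE)
  ssq <- l1^2 + l2^2 + l3^2
  if (any(ssq == 0))
    stop("FA undefined for an all-zero eigenvalue triple", call. = FALSE)
  fa <- sqrt(0.5) * sqrt((l1 - l2)^2 + (l2 - l3)^2 + (l3 - l1)^2) /
    sqrt(ssq)
  pmin(pmax(fa, 0), 1)  # clamp roundoff at the closed bounds
}

#' Axial diffusivity
#'
#' Diffusion along the principal fibre axis: the largest tensor
#' eigenvalue, \eqn{\lambda_1}.
#'
#' @inheritParams fractional_anisotropy
#' @return \eqn{\lambda_1} (same units as the input).
#' @export
axial_diffusivity <- function(lambda1, lambda2 = NULL, lambda3 = NULL) {
  if (is.null(lambda2) && length(lambda1) == 3L) return(max(lambda1))
  pmax(lambda1, lambda2, lambda3)
}

#' Arc length of a streamline polyline
#'
#' @param polyline numeric matrix, points x 3, in mm.
#' @return Sum of Euclidean segment lengths (mm).
#' @export
streamline_length <- function(polyline) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2L)
    stop("a streamline needs at least two points", call. = FALSE)
  d <- diff(polyline)
  sum(sqrt(rowSums(d^2)))
}

#' Tract set: streamlines and tensor samples for one pathway
#'
#' @param streamlines list of point x 3 matrices (mm).
#' @param eigenvalues matrix, one row of sorted `(lambda1, lambda2,
#'   lambda3)` per streamline (mm^2/s).
#' @param region_pair character vector `c(origin, target)`.
#' @param contact_area effective seed area in mm^2; the default is the
#'   disc of the 3 mm effective micro-contact diameter.
#'
#' @return An object of class `tract_set`. Empty tract sets (zero
#'   streamlines) are valid and flagged as carrying no connection.
#' @export
tract_set <- function(streamlines, eigenvalues,
                      region_pair = c(NA_character_, NA_character_),
                      contact_area = pi * 1.5^2) {
  if (contact_area <= 0) stop("`contact_area` must be > 0", call. = FALSE)
  n <- length(streamlines)
  eigenvalues <- matrix(as.numeric(eigenvalues), ncol = 3L)
  if (n > 0L && nrow(eigenvalues) != n)
    stop("need one eigenvalue triple per streamline", call. = FALSE)
  if (n > 0L) {
    if (any(vapply(streamlines, nrow, 1L) < 2L))
      stop("every streamline needs at least two points", call. = FALSE)
    if (any(apply(eigenvalues, 1L, is.unsorted)))
      eigenvalues <- t(apply(eigenvalues, 1L, sort, decreasing = TRUE))
  }
  structure(list(streamlines = streamlines, eigenvalues = eigenvalues,
                 region_pair = region_pair, contact_area = contact_area,
                 no_connection = (n == 0L)),
            class = "tract_set")
}

#' @export
print.tract_set <- function(x, ...) {
  cat("<tract_set> ", length(x$streamlines), " streamlines ",
      if (!anyNA(x$region_pair))
        paste0(x$region_pair[1], " -> ", x$region_pair[2], " "),
      "(seed area ", format(x$contact_area, digits = 4), " mm^2)",
      if (x$no_connection) " [no connection]", "\n", sep = "")
  invisible(x)
}

#' Fibre count per unit area
#'
#' Streamline count normalized by the effective seed contact area.
#'
#' @param tracts a [tract_set()].
#' @return Count per mm^2.
#' @export
fibres_per_area <- function(tracts) {
  stopifnot(inherits(tracts, "tract_set"))
  length(tracts$streamlines) / tracts$contact_area
}

#' Per-pathway structural summary
#'
#' Summarizes a tract set into the four structural measures used by the
#' association stage: FA and axial diffusivity as unweighted means over
#' per-streamline tensor samples, mean streamline length, and fibre count
#' per unit area.
#'
#' @param tracts a [tract_set()].
#' @return One-row data.frame with `fa`, `ad`, `n_per_area`, `length`,
#'   `n_streamlines`; all-`NA` metrics (with `n_per_area = 0`) for an
#'   empty tract set.
#' @export
pathway_dti_summary <- function(tracts) {
  stopifnot(inherits(tracts, "tract_set"))
  if (tracts$no_connection)
    return(data.frame(fa = NA_real_, ad = NA_real_, n_per_area = 0,
                      length = NA_real_, n_streamlines = 0L))
  ev <- tracts$eigenvalues
  fa <- mean(fractional_anisotropy(ev[, 1], ev[, 2], ev[, 3]))
  ad <- mean(ev[, 1])
  len <- mean(vapply(tracts$streamlines, streamline_length, numeric(1)))
  data.frame(fa = fa, ad = ad, n_per_area = fibres_per_area(tracts),
             length = len, n_streamlines = length(tracts$streamlines))
}

#' Read per-streamline tract tables
#'
#' Ingests a TSV with one row per streamline point (columns: subject,
#' hemisphere, pathway, streamline, point, x, y, z, lambda1, lambda2,
#' lambda3 — one tensor sample per streamline, repeated across its
#' points) and returns per-(subject, hemisphere, pathway) structural
#' summaries.
#'
#' @param path TSV file path.
#' @param contact_area effective seed area (mm^2).
#' @return data.frame of pathway summaries.
#' @export
read_tract_table <- function(path, contact_area = pi * 1.5^2) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("subject", "hemisphere", "pathway", "streamline", "point",
                "x", "y", "z", "lambda1", "lambda2", "lambda3")
  miss <- setdiff(required, names(tab))
  if (length(miss) > 0L)
    stop("tract table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  groups <- split(tab, interaction(tab$subject, tab$hemisphere,
                                   tab$pathway, drop = TRUE))
  out <- lapply(groups, function(g) {
    sl <- split(g[order(g$point), ], g$streamline[order(g$point)])
    streamlines <- lapply(sl, function(s) as.matrix(s[, c("x", "y", "z")]))
    ev <- t(vapply(sl, function(s)
      as.numeric(s[1L, c("lambda1", "lambda2", "lambda3")]), numeric(3)))
    ts <- tract_set(streamlines, ev, contact_area = contact_area)
    cbind(data.frame(subject = g$subject[1], hemisphere = g$hemisphere[1],
                     pathway = g$pathway[1], stringsAsFactors = FALSE),
          pathway_dti_summary(ts))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
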