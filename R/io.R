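#' Read detection histories from a long CSV
#'
#' Expects columns \code{site}, \code{visit}, \code{species}, \code{y}
#' (binary). Visits are indexed 1..J; sites may have unequal numbers of
#' visits — (site, visit) combinations absent from the file are marked as
#' missing in the visit mask and skipped by the model likelihood. Species
#' and site order follow first appearance in the file.
#'
#' Observed species with no detections at all are indistinguishable from
#' augmented pseudo-species, so by default they are dropped (with a
#' message) before \code{n_observed} is fixed; set
#' \code{drop_undetected = FALSE} to keep them as observed columns.
#'
#' @param path CSV path.
#' @param drop_undetected drop all-zero species from the observed set.
#' @return an [occ_data()]; dropped species names are in attribute
#'   \code{"dropped_species"}.
#' @export
read_detections <- function(path, drop_undetected = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "visit", "species", "y")
  if (!all(need %in% names(df))) {
    stop("CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!(df$y %in% c(0, 1)))
  if (length(bad)) {
    stop("non-binary detection values at rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  key <- paste(df$site, df$visit, df$species, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate (site, visit, species) records at rows: ",
         paste(utils::head(dup, 10), collapse = ", "), call. = FALSE)
  }
  sites <- unique(df$site)
  species <- unique(df$species)
  if (!is.numeric(df$visit) || any(df$visit < 1) ||
      any(df$visit != round(df$visit))) {
    stop("visit must be a positive integer index", call. = FALSE)
  }
  S <- length(sites); J <- max(df$visit); K <- length(species)
  i <- match(df$site, sites); j <- df$visit; k <- match(df$species, species)
  y <- array(0L, dim = c(S, J, K))
  y[cbind(i, j, k)] <- as.integer(df$y)
  mask <- matrix(FALSE, S, J)
  mask[unique(cbind(i, j))] <- TRUE
  dropped <- character()
  if (drop_undetected) {
    zero <- apply(y, 3, sum) == 0
    if (any(zero)) {
      dropped <- species[zero]
      message(sum(zero), " species with no detections dropped from the ",
              "observed set")
      y <- y[, , !zero, drop = FALSE]
      species <- species[!zero]
    }
  }
  out <- occ_data(y, mask = mask, species = species)
  attr(out, "site_ids") <- sites
  attr(out, "dropped_species") <- dropped
  out
}

#' Write detection histories to CSV
#'
#' \code{"long"} format writes one row per realized (site, visit, species)
#' with columns site, visit, species, y — the format [read_detections()]
#' reads back. \code{"wide"} writes one row per realized site x visit with
#' one column per species (the layout used by BUGS/JAGS-style array input).
#'
#' @param data an [occ_data()].
#' @param path output CSV path.
#' @param format \code{"long"} or \code{"wide"}.
#' @return \code{path}, invisibly.
#' @export
write_detections <- function(data, path, format = c("long", "wide")) {
  format <- match.arg(format)
  stopifnot(inherits(data, "occ_data"))
  S <- data$S; J <- data$J; K <- data$n_species
  vis <- which(data$mask, arr.ind = TRUE)
  vis <- vis[order(vis[, 1], vis[, 2]), , drop = FALSE]
  if (format == "long") {
    df <- data.frame(
      site = rep(vis[, 1], each = K),
      visit = rep(vis[, 2], each = K),
      species = rep(data$species, times = nrow(vis)),
      y = as.integer(t(matrix(data$y, S * J, K)[(vis[, 2] - 1) * S +
                                                  vis[, 1], ,
                                                drop = FALSE])))
  } else {
    m <- matrix(data$y, S * J, K)[(vis[, 2] - 1) * S + vis[, 1], ,
                                  drop = FALSE]
    colnames(m) <- data$species
    df <- data.frame(site = vis[, 1], visit = vis[, 2], m,
                     check.names = FALSE)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Standardize covariates to zero mean and unit variance
#'
#' Centers and scales each numeric column using the population variance
#' (divisor n). Scaling metadata is attached so values can be mapped back
#' to their original units. Optionally appends quadratic terms built from
#' the standardized linear terms (the squared term is deliberately not
#' re-standardized, keeping its coefficient interpretable against the
#' linear one).
#'
#' @param table data.frame of numeric covariates.
#' @param quadratic character vector of column names whose squares (named
#'   \code{<name>_sq}) are appended after standardization.
#' @return data.frame with attribute \code{"scaling"} (list of
#'   center/scale per column).
#' @export
standardize_covariates <- function(table, quadratic = character()) {
  stopifnot(is.data.frame(table), all(vapply(table, is.numeric, TRUE)),
            all(quadratic %in% names(table)))
  center <- vapply(table, mean, numeric(1))
  scale <- vapply(table, function(x) sqrt(mean((x - mean(x))^2)), numeric(1))
  if (any(scale == 0)) {
    stop("zero-variance column(s): ",
         paste(names(table)[scale == 0], collapse = ", "), call. = FALSE)
  }
  out <- as.data.frame(mapply(function(x, c, s) (x - c) / s, table, center,
                              scale, SIMPLIFY = FALSE))
  for (q in quadratic) out[[paste0(q, "_sq")]] <- out[[q]]^2
  attr(out, "scaling") <- list(center = center, scale = scale)
  out
}

#' Back-transform standardized covariates
#'
#' @param table standardized data.frame from [standardize_covariates()].
#' @param scaling scaling metadata (defaults to the attribute on
#'   \code{table}). Quadratic columns are dropped.
#' @return data.frame in original units.
#' @export
unstandardize_covariates <- function(table,
                                     scaling = attr(table, "scaling")) {
  stopifnot(!is.null(scaling))
  nms <- names(scaling$center)
  out <- as.data.frame(mapply(function(nm) {
    table[[nm]] * scaling$scale[[nm]] + scaling$center[[nm]]
  }, nms, SIMPLIFY = FALSE))
  names(out) <- nms
  out
}

#' Write / read a scenario configuration as YAML
#'
#' @param spec an [occ_scenario()].
#' @param path YAML file path.
#' @return \code{write_scenario}: \code{path} invisibly;
#'   \code{read_scenario}: the reconstructed [occ_scenario()].
#' @export
write_scenario <- function(spec, path) {
  stopifnot(inherits(spec, "occ_scenario"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  occ_scenario(n_species = x$n_species, occ_mu = x$occ_mu,
               occ_sigma = x$occ_sigma, det_family = x$det_family,
               det_params = x$det_params, S = x$S, J = x$J,
               seed = x$seed, id = x$id)
}
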