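# Readers and writers for the plain-text formats the pipeline exchanges:
# design CSVs, compound-library CSVs, model coefficients as JSON.

DESIGN_HEADER <- c("run", "ec_pct", "time_min", "temp_c",
                   "coded_x1", "coded_x2", "coded_x3")

#' Read a design table CSV
#'
#' Expects the header `run,ec_pct,time_min,temp_c,coded_x1,coded_x2,
#' coded_x3`; any further columns (responses, SDs, external predictions)
#' are carried along untouched. Factor specifications are reconstructed
#' from the coded/actual correspondence.
#'
#' @param path CSV file path.
#' @return A `bbd_design` data frame (extra columns preserved) with the
#'   reconstructed factors in `attr(, "factors")`.
#' @export
read_design_csv <- function(path) {
  header <- names(utils::read.csv(path, nrows = 1L, check.names = FALSE))
  if (!identical(header[seq_along(DESIGN_HEADER)], DESIGN_HEADER)) {
    stop(sprintf("malformed design CSV '%s': header must start with %s",
                 path, paste(DESIGN_HEADER, collapse = ",")), call. = FALSE)
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  factors <- lapply(c(ec_pct = "ec_pct", time_min = "time_min",
                      temp_c = "temp_c"), function(col) col)
  spec <- vector("list", 3L)
  actual_cols <- c("ec_pct", "time_min", "temp_c")
  coded_cols <- c("coded_x1", "coded_x2", "coded_x3")
  for (j in 1:3) {
    a <- d[[actual_cols[j]]]; cd <- d[[coded_cols[j]]]
    center <- unique(a[cd == 0]); high <- unique(a[cd == 1])
    if (length(center) != 1L || length(high) != 1L) {
      stop("cannot reconstruct factor levels from the design CSV",
           call. = FALSE)
    }
    spec[[j]] <- factor_spec(actual_cols[j], 2 * center - high, high)
  }
  out <- d
  names(out)[match(coded_cols, names(out))] <- c("x1", "x2", "x3")
  out$is_center <- out$x1 == 0 & out$x2 == 0 & out$x3 == 0
  structure(out, factors = spec, class = c("bbd_design", "data.frame"))
}

#' Write a design table (plus optional response columns) as CSV
#'
#' @param design A `bbd_design`.
#' @param path Output file path.
#' @param responses Optional data frame of extra columns to append.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path, responses = NULL) {
  factors <- attr(design, "factors")
  out <- data.frame(run = design$run)
  nm <- vapply(factors, `[[`, character(1), "name")
  for (j in 1:3) out[[DESIGN_HEADER[j + 1L]]] <- design[[nm[j]]]
  out$coded_x1 <- design$x1; out$coded_x2 <- design$x2
  out$coded_x3 <- design$x3
  extra <- setdiff(names(design), c("run", nm, "x1", "x2", "x3", "is_center"))
  for (col in extra) out[[col]] <- design[[col]]
  if (!is.null(responses)) out <- cbind(out, responses)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a compound-library CSV
#'
#' Expects columns `name,class,formula,observed_mz,fragments,confidence`
#' with semicolon-separated fragment lists.
#'
#' @param path CSV file path.
#' @return Data frame; `confidence` is an integer in 1..3.
#' @export
read_compound_library <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "class", "formula", "observed_mz", "fragments",
            "confidence")
  if (!all(need %in% names(d))) {
    stop(sprintf("malformed library CSV '%s': missing column(s) %s", path,
                 paste(setdiff(need, names(d)), collapse = ", ")),
         call. = FALSE)
  }
  d$confidence <- as.integer(d$confidence)
  if (any(!d$confidence %in% 1:3)) {
    stop("confidence levels must be 1, 2 or 3", call. = FALSE)
  }
  d
}

#' Write an annotated compound library as CSV
#'
#' @param library Data frame as returned by [annotate_library()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_compound_library <- function(library, path) {
  utils::write.csv(library, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Serialize fitted quadratic models as JSON
#'
#' @param models Named list of `rsm_quadratic` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_models_json <- function(models, path) {
  payload <- lapply(models, function(m) {
    list(response = m$response, units = m$units,
         coefficients = as.list(m$coefficients))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_models_json
#' @return For the reader, a named list of `rsm_quadratic` models.
#' @export
read_models_json <- function(path) {
  payload <- jsonlite::read_json(path)
  lapply(payload, function(p) {
    quadratic_model(unlist(p$coefficients), response = p$response,
                    units = if (is.null(p$units)) "" else p$units)
  })
}
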