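#' Read a derived-trait definition table
#'
#' Derived glycan traits are summaries of peaks that share a structural
#' feature (branching, galactosylation, sialylation, fucose position, ...).
#' Definitions are declarative data, not code: a CSV with columns
#' `trait_id, family, formula`, where `formula` is an arithmetic expression
#' over peak ids restricted to sums, differences, scalar multiples and ratios
#' of sums, e.g. `100*(GP30+GP31+GP32)/TOTAL`. The token `TOTAL` stands for
#' the sum of all panel peaks.
#'
#' The shipped default table (see [default_trait_definitions()]) carries 21
#' traits in the six canonical families; its formulas follow common plasma
#' N-glycome conventions and are meant to be overridden when a
#' laboratory-specific assignment table is available.
#'
#' @param path CSV file path.
#' @param peaks valid peak panel the formulas may reference.
#' @return A data.frame of class `trait_definitions` with a parsed
#'   expression per trait (list-column `expr`).
#' @export
read_trait_definitions <- function(path, peaks = default_peak_panel()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE, quote = "\"")
  need <- c("trait_id", "family", "formula")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trait table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$trait_id)) stop("duplicate trait ids")
  exprs <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    exprs[[i]] <- tryCatch(
      parse_trait_formula(df$formula[i], peaks),
      error = function(e) stop("trait table line ", i + 1L, " (",
                               df$trait_id[i], "): ", conditionMessage(e),
                               call. = FALSE))
  }
  df$expr <- exprs
  class(df) <- c("trait_definitions", "data.frame")
  df
}

#' Default 21-trait definition table
#'
#' Convention-based formulas (not a published laboratory assignment) for 21
#' derived traits over the `GP1..GP39` panel, grouped under the six families:
#' branching, degree of branching, galactosylation, sialylation, sialylation
#' of biantennary, and fucose position.
#'
#' @inheritParams read_trait_definitions
#' @export
default_trait_definitions <- function(peaks = default_peak_panel()) {
  read_trait_definitions(
    system.file("extdata", "derived_traits.csv", package = "glycoblock",
                mustWork = TRUE),
    peaks = peaks)
}

# Parse a trait formula into an R expression, admitting only +, -, *, /,
# parentheses, numeric literals and known peak symbols (plus TOTAL).
parse_trait_formula <- function(text, peaks) {
  ex <- tryCatch(str2lang(text),
                 error = function(e) stop("malformed formula: ", text,
                                          call. = FALSE))
  allowed <- c(peaks, "TOTAL")
  check <- function(e) {
    if (is.numeric(e)) return(invisible())
    if (is.symbol(e)) {
      s <- as.character(e)
      if (!s %in% allowed)
        stop("unknown peak token '", s, "' in formula: ", text, call. = FALSE)
      return(invisible())
    }
    if (is.call(e)) {
      op <- as.character(e[[1L]])
      if (!op %in% c("+", "-", "*", "/", "("))
        stop("operator '", op, "' not allowed in trait formulas", call. = FALSE)
      for (k in seq(2L, length(e))) check(e[[k]])
      return(invisible())
    }
    stop("malformed formula: ", text, call. = FALSE)
  }
  check(ex)
  ex
}

#' Compute derived traits from a peak matrix
#'
#' Evaluates each trait formula per sample (vectorised exact arithmetic on
#' the parsed expression). Inputs are expected on the compositional
#' (percent-of-total) scale; a warning is issued otherwise because ratio
#' traits lose their usual interpretation on transformed scales.
#'
#' @param X a [glycan_matrix()].
#' @param defs a `trait_definitions` table; defaults to the shipped table.
#' @return A samples-by-traits numeric matrix of class `derived_traits` with
#'   the definition table attached as attribute `provenance`.
#' @export
compute_traits <- function(X, defs = default_trait_definitions()) {
  stopifnot(inherits(defs, "trait_definitions"))
  referenced <- setdiff(unlist(lapply(defs$expr, all.vars)), "TOTAL")
  absent <- setdiff(referenced, colnames(X))
  if (length(absent))
    stop("peaks referenced by traits but absent from the matrix: ",
         paste(absent, collapse = ", "))
  if (!isTRUE(attr(X, "compositional")))
    warning("computing traits on a non-compositional matrix; ",
            "ratio traits may not be interpretable")
  env <- new.env(parent = baseenv())
  for (p in colnames(X)) assign(p, unclass(X)[, p], envir = env)
  assign("TOTAL", rowSums(unclass(X)), envir = env)
  out <- matrix(NA_real_, nrow(X), nrow(defs),
                dimnames = list(rownames(X), defs$trait_id))
  for (i in seq_len(nrow(defs))) {
    v <- eval(defs$expr[[i]], env)
    bad <- !is.finite(v)
    if (any(bad))
      stop("non-finite value for trait ", defs$trait_id[i],
           " in sample(s): ", paste(rownames(X)[bad], collapse = ", "),
           " (division by zero?)")
    out[, i] <- v
  }
  structure(out, class = c("derived_traits", "matrix", "array"),
            provenance = defs[c("trait_id", "family", "formula")])
}
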