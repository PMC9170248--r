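#' Measured quantity with dispersion
#'
#' The atom of the estimation chain: a value on its printed scale, an
#' uncertainty (`err`) that is either a standard error of the mean (`"SEM"`),
#' a standard deviation (`"SD"`), or absent (`"none"`), an optional sample
#' size, and a unit string.
#'
#' @param value numeric scalar.
#' @param err non-negative uncertainty on the same scale as `value`.
#' @param err_kind one of `"SEM"`, `"SD"`, `"none"`.
#' @param n sample size behind the estimate, or `NA`.
#' @param units unit string, e.g. `"nm"`, `"pS"`, `"1/um^2"`, `""`.
#' @return An object of class `quantity`.
#' @examples
#' quantity(477, 19.5, "SEM", n = 135, units = "nm")
#' @export
quantity <- function(value, err = 0, err_kind = c("none", "SEM", "SD"),
                     n = NA_integer_, units = "") {
  err_kind <- match.arg(err_kind)
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  stopifnot(is.numeric(err), length(err) == 1L, err >= 0)
  if (err_kind == "none" && err != 0)
    stop("err must be 0 when err_kind is 'none'")
  if (err > 0 && err_kind == "none") err_kind <- "SD"
  structure(
    list(value = value, err = err, err_kind = err_kind,
         n = if (is.na(n)) NA_integer_ else as.integer(n), units = units),
    class = "quantity"
  )
}

#' @export
print.quantity <- function(x, ...) {
  s <- format_quantity(x)
  cat(s, "\n")
  invisible(x)
}

#' Format a quantity for display
#' @param x a [quantity()].
#' @return A single character string like `"477 +/- 19.5 nm (mean +/- SEM, n = 135)"`.
#' @export
format_quantity <- function(x) {
  s <- format(x$value)
  if (x$err_kind != "none") {
    s <- paste0(s, " ± ", format(x$err))
  }
  if (nzchar(x$units)) s <- paste(s, x$units)
  if (x$err_kind != "none") {
    tail <- paste0("mean ± ", x$err_kind)
    if (!is.na(x$n)) tail <- paste0(tail, ", n = ", x$n)
    s <- paste0(s, " (", tail, ")")
  }
  s
}

#' Relative uncertainty of a quantity
#' @param q a [quantity()].
#' @return `q$err / |q$value|` (0 if errorless).
#' @export
rel_err <- function(q) {
  stopifnot(inherits(q, "quantity"))
  if (q$err == 0) return(0)
  q$err / abs(q$value)
}

# ---- unit algebra ----------------------------------------------------------
# Minimal named-exponent unit bookkeeping: enough to verify that nm/nm
# cancels, that dimensionless x pS gives pS, and to format results.

parse_unit <- function(u) {
  if (is.null(u) || !nzchar(u)) return(stats::setNames(numeric(0), character(0)))
  u <- gsub("\\s+", "", u)
  # split a "1/x" or "a/b" form
  parts <- strsplit(u, "/", fixed = TRUE)[[1]]
  out <- numeric(0)
  add <- function(out, tok, sign) {
    if (tok == "1" || tok == "") return(out)
    m <- regmatches(tok, regexec("^([A-Za-z%]+)(\\^(-?[0-9]+))?$", tok))[[1]]
    if (length(m) == 0) stop("cannot parse unit token: ", tok)
    base <- m[2]
    expo <- if (nzchar(m[4])) as.numeric(m[4]) else 1
    out[base] <- (if (base %in% names(out)) out[base] else 0) + sign * expo
    out
  }
  out <- add(out, parts[1], +1)
  if (length(parts) > 1) for (p in parts[-1]) out <- add(out, p, -1)
  out[out != 0]
}

format_unit <- function(ex) {
  ex <- ex[ex != 0]
  if (length(ex) == 0) return("")
  fmt1 <- function(nm, e) if (e == 1) nm else paste0(nm, "^", e)
  num <- ex[ex > 0]; den <- ex[ex < 0]
  ns <- paste(mapply(fmt1, names(num), num), collapse = " ")
  if (length(den) == 0) return(ns)
  ds <- paste(mapply(fmt1, names(den), -den), collapse = " ")
  if (length(num) == 0) return(paste0("1/", ds))
  paste0(ns, "/", ds)
}

combine_units <- function(quantities, exponents) {
  ex <- numeric(0)
  for (i in seq_along(quantities)) {
    ui <- parse_unit(quantities[[i]]$units)
    for (nm in names(ui)) {
      ex[nm] <- (if (nm %in% names(ex)) ex[nm] else 0) + exponents[i] * ui[nm]
    }
  }
  format_unit(ex)
}

# ---- propagation -----------------------------------------------------------

#' Propagate uncertainty through a product of powers
#'
#' Computes `prod(value_i ^ e_i)` for a list of quantities and propagates the
#' relative uncertainties. Two conventions are supported:
#' \describe{
#'   \item{`"quadrature"`}{relative errors add in quadrature ignoring the
#'     exponent magnitude, `sqrt(sum(rel_i^2))` — the convention that
#'     reproduces the printed SEMs of the rod/cone coupling chain;}
#'   \item{`"delta"`}{the first-order delta method,
#'     `sqrt(sum((e_i * rel_i)^2))`.}
#' }
#' Unit strings are combined algebraically (so `nm/nm` cancels and a
#' dimensionless factor times `pS` stays `pS`).
#'
#' @param quantities list of [quantity()] objects.
#' @param exponents numeric vector of signed exponents, one per quantity.
#' @param mode `"quadrature"` or `"delta"`.
#' @param units optional unit string override for the result.
#' @param n sample size to attach to the result (default `NA`).
#' @return A [quantity()] with `err_kind = "SEM"` if any input carries error.
#' @examples
#' L <- quantity(477, 19.5, "SEM", units = "nm")
#' d <- quantity(9.45, 0.296, "SEM", units = "nm")
#' propagate_product(list(L, d), c(1, -1))  # 50.5 +/- 2.60 connexons
#' @export
propagate_product <- function(quantities, exponents,
                              mode = c("quadrature", "delta"),
                              units = NULL, n = NA_integer_) {
  mode <- match.arg(mode)
  stopifnot(length(quantities) == length(exponents), length(quantities) >= 1)
  vals <- vapply(quantities, function(q) q$value, numeric(1))
  if (any(vals == 0 & exponents < 0))
    stop("division by zero-valued quantity")
  value <- prod(vals ^ exponents)
  rels <- vapply(quantities, rel_err, numeric(1))
  rel_out <- switch(mode,
    quadrature = sqrt(sum(rels^2)),
    delta      = sqrt(sum((exponents * rels)^2))
  )
  err <- abs(value) * rel_out
  if (is.null(units)) units <- combine_units(quantities, exponents)
  kinds <- vapply(quantities, function(q) q$err_kind, character(1))
  kind <- if (err == 0) "none" else if (any(kinds == "SEM")) "SEM" else "SD"
  quantity(value, err, kind, n = n, units = units)
}

# ---- printed-precision rounding -------------------------------------------

#' Round to significant figures, half away from zero
#'
#' `signif()` rounds half to even (1.70 x 50.5 = 85.85 becomes 85.8); printed
#' scientific tables round half away from zero (85.9). This helper matches the
#' latter convention.
#'
#' @param x numeric.
#' @param digits number of significant figures.
#' @return `x` rounded to `digits` significant figures.
#' @export
signif_half_up <- function(x, digits = 3) {
  out <- x
  nz <- is.finite(x) & x != 0
  if (any(nz)) {
    e <- floor(log10(abs(x[nz]))) - digits + 1
    sc <- 10^e
    out[nz] <- sign(x[nz]) * floor(abs(x[nz]) / sc + 0.5 + 1e-12) * sc
  }
  out
}

# Round a quantity to the precision at which the source tables print values:
# 3 significant figures, except 4 for magnitudes >= 1000 (conductances print
# as 1228, 1312).
round_printed <- function(q) {
  digs <- function(v) if (abs(v) >= 1000) 4 else 3
  v <- signif_half_up(q$value, digs(q$value))
  # keep the *relative* error consistent with the rounded value before
  # rounding the error itself (85.9 x 0.0804 -> 6.91, not 85.85 x 0.0804)
  e <- if (q$err > 0 && q$value != 0)
    signif_half_up(q$err * abs(v / q$value), digs(q$err)) else 0
  quantity(v, e, q$err_kind, n = q$n, units = q$units)
}
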