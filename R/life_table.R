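#' Annual life tables
#'
#' A life table is the standard demographic summary of age-specific
#' mortality: for each integer age `x` it gives `qx`, the conditional
#' probability that an individual alive at exact age `x` dies before age
#' `x + 1`. The Markov extrapolation consumes these probabilities directly
#' as the unrevised-to-dead and revised-to-dead transitions.
#'
#' `life_table()` constructs and validates a table from vectors of ages and
#' probabilities; ages must be consecutive integers, every `qx` must lie in
#' \[0, 1\], and the final `qx` must equal 1 so the table closes (no mass
#' survives past the last age).
#'
#' @param ages Integer vector of consecutive ages.
#' @param qx Numeric vector of annual conditional death probabilities, same
#'   length as `ages`; the last entry must be 1.
#' @return A data frame of class `life_table` with columns `age` and `qx`.
#' @seealso [makeham_life_table()] for the parametric fixture,
#'   [read_life_table()] for the CSV interface.
#' @examples
#' lt <- life_table(ages = 0:3, qx = c(0.01, 0.02, 0.05, 1))
#' qx_at(lt, 2)
#' @export
life_table <- function(ages, qx) {
  ages <- as.integer(ages)
  qx <- as.numeric(qx)
  if (length(ages) != length(qx) || length(ages) < 1L)
    stop("`ages` and `qx` must be non-empty vectors of equal length")
  if (any(diff(ages) != 1L))
    stop("`ages` must be consecutive integers with no gaps")
  if (any(!is.finite(qx)) || any(qx < 0) || any(qx > 1))
    stop("every `qx` must be a finite probability in [0, 1]")
  if (qx[length(qx)] != 1)
    stop("the last qx must be 1 so the table closes at its maximum age")
  out <- data.frame(age = ages, qx = qx)
  class(out) <- c("life_table", "data.frame")
  out
}

#' Gompertz-Makeham mortality parameters
#'
#' The Gompertz-Makeham law models the adult human mortality hazard as
#' `A + B * exp(C * age)`: an age-independent background component `A` plus
#' a senescent component growing exponentially with age at log-slope `C`.
#' It is the standard two-line parametric account of national life-table
#' mortality and is used here to generate a stand-in for a national table.
#'
#' @param A Background hazard per year (>= 0).
#' @param B Senescent hazard scale per year (> 0).
#' @param C Log-slope of the senescent hazard per year of age (> 0).
#' @return A list of class `makeham_params`.
#' @export
makeham_params <- function(A = 2.0e-4, B = 2.5e-5, C = 0.095) {
  for (nm in c("A", "B", "C")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("Makeham parameter `", nm, "` must be a finite number")
  }
  if (A < 0) stop("Makeham parameter `A` must be >= 0")
  if (B <= 0) stop("Makeham parameter `B` must be > 0")
  if (C <= 0) stop("Makeham parameter `C` must be > 0")
  structure(list(A = A, B = B, C = C), class = "makeham_params")
}

#' Build a life table from the Gompertz-Makeham law
#'
#' Integrates the Makeham hazard over each one-year age interval to obtain
#' the annual death probability
#' `qx(age) = 1 - exp(-A - (B/C) * exp(C*age) * (exp(C) - 1))`,
#' and closes the table by forcing `qx = 1` at `max_age`. The default
#' parameters are calibrated so that remaining life expectancy at ages
#' 55/65/75/85 is roughly 27/19/12/7 years, in line with recent
#' national-statistics tables for a sex-pooled population.
#'
#' @param params A [makeham_params()] object.
#' @param max_age Last age of the table (default 110); `qx` is forced to 1
#'   there.
#' @param start_age First age of the table (default 0).
#' @return A [life_table()].
#' @examples
#' lt <- makeham_life_table()
#' life_expectancy(lt, 65)
#' @export
makeham_life_table <- function(params = makeham_params(), max_age = 110L,
                               start_age = 0L) {
  if (!inherits(params, "makeham_params")) params <- do.call(makeham_params, as.list(params))
  max_age <- as.integer(max_age)
  if (max_age < 1L || max_age <= start_age)
    stop("`max_age` must be a positive integer above `start_age`")
  ages <- seq.int(start_age, max_age)
  H <- params$A + (params$B / params$C) * exp(params$C * ages) * (exp(params$C) - 1)
  qx <- pmin(pmax(1 - exp(-H), 0), 1)
  qx[length(qx)] <- 1
  life_table(ages, qx)
}

#' Look up the annual death probability at an age
#'
#' @param lt A [life_table()].
#' @param age Integer age(s); must be covered by the table.
#' @return Numeric vector of `qx` values.
#' @export
qx_at <- function(lt, age) {
  stopifnot(inherits(lt, "life_table"))
  idx <- match(as.integer(age), lt$age)
  if (anyNA(idx)) {
    missing <- sort(unique(age[is.na(idx)]))
    stop("life table does not cover age(s) ", paste(missing, collapse = ", "),
         " (table spans ", min(lt$age), "-", max(lt$age), ")")
  }
  lt$qx[idx]
}

#' Remaining life expectancy from a life table
#'
#' Accumulates the survival curve implied by the annual probabilities from
#' the given age, with a half-year continuity correction for the year of
#' death (deaths assumed mid-year on average).
#'
#' @param lt A [life_table()].
#' @param age Integer starting age.
#' @return Expected remaining years of life.
#' @export
life_expectancy <- function(lt, age) {
  stopifnot(inherits(lt, "life_table"))
  if (!(age %in% lt$age)) stop("age ", age, " not covered by the life table")
  px <- 1 - lt$qx[lt$age >= age]
  sum(cumprod(px)) + 0.5
}

#' Read / write a life-table CSV
#'
#' The CSV dialect is `age,qx`: one row per consecutive integer age, `.`
#' decimal, last row's `qx` equal to 1. This is the override point for users
#' supplying a real national life table in place of the Makeham fixture.
#'
#' @param path Path to the CSV file.
#' @return `read_life_table()` returns a [life_table()];
#'   `write_life_table()` returns `path` invisibly.
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age", "qx") %in% names(df)))
    stop("life-table CSV must have columns `age` and `qx` (file: ", path, ")")
  life_table(df$age, df$qx)
}

#' @rdname read_life_table
#' @param lt A [life_table()] to write.
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "life_table"))
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.life_table <- function(x, ...) {
  cat("Annual life table: ages ", min(x$age), "-", max(x$age),
      ", qx ", signif(min(x$qx), 3), "-1\n", sep = "")
  invisible(x)
}
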