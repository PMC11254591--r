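#' @keywords internal
REQUIRED_COST_KEYS <- c(
  "psa_test", "stockholm3", "mri", "biopsy", "rp", "rt", "plnd", "adt",
  "arpi", "chemo_cycle", "immune", "parp", "lu_psma", "ra223", "psma_pet",
  "osteoprotective", "palliative", "end_of_life", "trus"
)

#' Unit-cost table for diagnostics, treatments and supportive care
#'
#' Builds a validated cost table from named unit costs (EUR). The packaged
#' defaults are consolidated average European health-sector costs per unit or
#' per year of therapy, with standard deviations where reported.
#'
#' @param unit_cost named numeric vector of unit costs in EUR; must contain all
#'   keys in `REQUIRED_COST_KEYS`.
#' @param sd named numeric vector of standard deviations (EUR); `NA` where not
#'   available.
#' @param basis named character vector giving the costing basis of each item:
#'   `"per_event"`, `"per_year"` or `"total_course"`.
#' @return an object of class `cost_table`: a data frame with columns
#'   `item`, `unit_cost`, `sd`, `basis`.
#' @examples
#' costs <- default_costs()
#' cost_of(costs, "stockholm3")  # 400
#' @export
cost_table <- function(unit_cost, sd = NULL, basis = NULL) {
  missing_keys <- setdiff(REQUIRED_COST_KEYS, names(unit_cost))
  if (length(missing_keys) > 0L) {
    stop("incomplete cost table: missing key(s) ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  items <- names(unit_cost)
  if (any(!is.finite(unit_cost)) || any(unit_cost < 0)) {
    bad <- items[!is.finite(unit_cost) | unit_cost < 0]
    stop("validation error at costs.", bad[1L], ": unit_cost must be >= 0",
         call. = FALSE)
  }
  sd <- sd %||% stats::setNames(rep(NA_real_, length(items)), items)
  if (any(!is.na(sd[items]) & sd[items] < 0)) {
    stop("validation error: sd must be >= 0 when present", call. = FALSE)
  }
  basis <- basis %||% stats::setNames(rep("per_event", length(items)), items)
  out <- data.frame(
    item = items,
    unit_cost = as.numeric(unit_cost[items]),
    sd = as.numeric(sd[items]),
    basis = as.character(basis[items]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("cost_table", class(out))
  out
}

#' Packaged default unit costs
#'
#' Consolidated average costs across eight European health care systems
#' (France, Germany, Italy, Norway, the Netherlands, Switzerland, UK, Sweden),
#' in EUR. Annual-cost items (ADT, ARPI, immune, PARP, radiopharmaceuticals,
#' osteoprotective medication) are per patient-year on therapy; palliative and
#' end-of-life care are one-time totals; chemotherapy is one full course.
#'
#' @return a [cost_table()].
#' @export
default_costs <- function() {
  vals <- c(
    psa_test = 29, stockholm3 = 400, mri = 406, biopsy = 1347,
    rp = 10832, rt = 7726, plnd = 1500, adt = 2370, arpi = 8905,
    chemo_cycle = 15519, immune = 104264, parp = 51216,
    lu_psma = 90106, ra223 = 25692, psma_pet = 1498,
    osteoprotective = 1058, palliative = 27980, end_of_life = 13939,
    trus = 100
  )
  sds <- c(
    psa_test = 12, stockholm3 = NA, mri = 169, biopsy = 1540,
    rp = 3464, rt = 3334, plnd = NA, adt = 1413, arpi = 18886,
    chemo_cycle = 9476, immune = 28046, parp = 15444,
    lu_psma = 36598, ra223 = 5825, psma_pet = 1209,
    osteoprotective = 1031, palliative = 16067, end_of_life = 13179,
    trus = NA
  )
  basis <- c(
    psa_test = "per_event", stockholm3 = "per_event", mri = "per_event",
    biopsy = "per_event", rp = "per_event", rt = "per_event",
    plnd = "per_event", adt = "per_year", arpi = "per_year",
    chemo_cycle = "total_course", immune = "per_year", parp = "per_year",
    lu_psma = "per_year", ra223 = "per_year", psma_pet = "per_event",
    osteoprotective = "per_year", palliative = "total_course",
    end_of_life = "total_course", trus = "per_event"
  )
  cost_table(vals, sds, basis)
}

#' Look up a unit cost
#'
#' @param costs a [cost_table()].
#' @param key item name (one of `REQUIRED_COST_KEYS`).
#' @return the unit cost in EUR.
#' @export
cost_of <- function(costs, key) {
  i <- match(key, costs$item)
  if (anyNA(i)) {
    stop("unknown cost key: ", paste(key[is.na(i)], collapse = ", "), call. = FALSE)
  }
  costs$unit_cost[i]
}

#' @export
print.cost_table <- function(x, ...) {
  cat("<cost_table> ", nrow(x), " items (EUR)\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
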