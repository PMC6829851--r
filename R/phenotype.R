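#' Survival phenotype under the counting-process formulation
#'
#' Bundles per-individual left-truncation ("entry") and event/censoring
#' ("exit") ages with an event indicator. Entry is the age at which an
#' individual becomes observable (in EHR cohorts, age at first visit); an
#' individual contributes to the risk set at time t only when
#' `entry < t <= exit`.
#'
#' @param entry_age numeric vector of entry (left-truncation) ages.
#' @param exit_age numeric vector of event or censoring ages; must exceed
#'   `entry_age` elementwise.
#' @param event_status 0/1 (or logical) event indicator: 1 = event observed
#'   at `exit_age`, 0 = right-censored.
#' @param id optional individual identifiers (default `seq_along(entry_age)`).
#' @return An object of class `survival_phenotype`: a data frame with columns
#'   `id`, `entry_age`, `exit_age`, `event_status`.
#' @examples
#' survival_phenotype(c(0, 0.5), c(2, 3), c(1, 0))
#' @export
survival_phenotype <- function(entry_age, exit_age, event_status,
                               id = seq_along(entry_age)) {
  entry_age <- as.numeric(entry_age)
  exit_age <- as.numeric(exit_age)
  event_status <- as.integer(event_status)
  n <- length(entry_age)
  if (length(exit_age) != n || length(event_status) != n || length(id) != n)
    stop("entry_age, exit_age, event_status and id must have equal length")
  if (anyNA(entry_age) || anyNA(exit_age) || anyNA(event_status))
    stop("survival phenotype must not contain missing values")
  if (!all(event_status %in% c(0L, 1L)))
    stop("event_status must be 0/1")
  if (any(entry_age >= exit_age))
    stop("entry_age must be strictly less than exit_age for every individual")
  structure(
    data.frame(id = as.character(id), entry_age = entry_age,
               exit_age = exit_age, event_status = event_status,
               stringsAsFactors = FALSE),
    class = c("survival_phenotype", "data.frame")
  )
}

#' @export
print.survival_phenotype <- function(x, ...) {
  cat(sprintf("Survival phenotype: %d individuals, %d events (%.1f%%)\n",
              nrow(x), sum(x$event_status),
              100 * mean(x$event_status)))
  cat(sprintf("  entry age: [%.3g, %.3g]   exit age: [%.3g, %.3g]\n",
              min(x$entry_age), max(x$entry_age),
              min(x$exit_age), max(x$exit_age)))
  invisible(x)
}

#' Read / write a survival phenotype TSV
#'
#' The TSV dialect is tab-separated with a header row and columns
#' `id`, `entry_age`, `exit_age`, `event` (missing values written as `NA`,
#' though a valid phenotype contains none).
#'
#' @param path file path.
#' @return `read_phenotype()` returns a [survival_phenotype].
#' @export
read_phenotype <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "entry_age", "exit_age", "event")
  if (!all(need %in% names(d)))
    stop("phenotype TSV must have columns: ", paste(need, collapse = ", "))
  survival_phenotype(d$entry_age, d$exit_age, d$event, id = d$id)
}

#' @rdname read_phenotype
#' @param pheno a [survival_phenotype].
#' @export
write_phenotype <- function(pheno, path) {
  stopifnot(inherits(pheno, "survival_phenotype"))
  d <- data.frame(id = pheno$id, entry_age = pheno$entry_age,
                  exit_age = pheno$exit_age, event = pheno$event_status)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
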