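# Age-by-stage probability tables and stage imputation.
#
# Parasitized hosts are paralyzed at attack, so their molted head
# capsules record the stage reached; unparasitized hosts develop on and
# their stage on the exposure day is never observed. The hazard
# analysis needs a stage for every host, so unobserved stages are
# sampled from empirical (quality, age) -> stage distributions built
# from reference rearing data.

#' Map a head-capsule count to a developmental stage
#'
#' A host molts its head capsule at each larval molt, so `n` recovered
#' capsules place a larva in instar `n + 1`; four capsules mean the
#' final larval molt happened and the host is a pupa, or an adult if
#' adult morphology is present.
#'
#' @param n_capsules Integer count(s) of molted head capsules, 0--4.
#' @param is_pupa_or_adult Logical flag(s): adult morphology observed.
#' @return Character stage label(s).
#' @examples
#' stage_from_head_capsules(0)            # "L1"
#' stage_from_head_capsules(4)            # "P"
#' stage_from_head_capsules(4, TRUE)      # "A"
#' @export
stage_from_head_capsules <- function(n_capsules, is_pupa_or_adult = FALSE) {
  n_capsules <- as.integer(n_capsules)
  if (any(is.na(n_capsules)) || any(n_capsules < 0L) || any(n_capsules > 4L))
    stop("head-capsule count must be an integer in 0..4")
  out <- STAGE_LEVELS[n_capsules + 1L]
  adult <- n_capsules == 4L & rep_len(is_pupa_or_adult, length(n_capsules))
  out[adult] <- "A"
  out
}

#' Estimate age-by-stage probability tables from reference data
#'
#' For every (quality, age) cell present in the reference development
#' table, the empirical relative frequencies of the six stages.
#'
#' @param reference Data frame with columns `quality`, `age`, `stage`
#'   (see [generate_reference_table()]).
#' @param provenance Identifier recorded on the table (default the
#'   deparsed argument).
#' @return A `stage_distribution` object: data frame with `quality`,
#'   `age`, probability columns `p_L1`..`p_A`, and cell count `n`.
#' @export
estimate_stage_distribution <- function(reference,
                                        provenance =
                                          deparse(substitute(reference))) {
  stopifnot(is.data.frame(reference),
            all(c("quality", "age", "stage") %in% names(reference)))
  if (nrow(reference) == 0L) stop("reference table is empty")
  stage <- as_stage(reference$stage)
  if (anyNA(stage)) stop("reference table has missing stages")
  key <- paste(reference$quality, reference$age, sep = "\r")
  counts <- table(key, stage)               # cells x 6, fixed stage order
  probs <- counts / rowSums(counts)
  cell <- do.call(rbind, strsplit(rownames(counts), "\r", fixed = TRUE))
  out <- data.frame(quality = cell[, 1L],
                    age = as.integer(cell[, 2L]),
                    stringsAsFactors = FALSE)
  pm <- matrix(as.numeric(probs), nrow = nrow(probs))
  colnames(pm) <- paste0("p_", STAGE_LEVELS)
  out <- cbind(out, pm)
  out$n <- as.integer(rowSums(counts))
  out <- out[order(out$quality, out$age), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("stage_distribution", "data.frame"),
            provenance = provenance)
}

# probability matrix (cells x 6) of a stage_distribution
prob_matrix <- function(table) {
  as.matrix(table[, paste0("p_", STAGE_LEVELS)])
}

# match (quality, age) pairs to table rows; error (or nearest-age
# fallback) on misses
match_cells <- function(table, quality, age, nearest_age = FALSE) {
  key <- paste(table$quality, table$age, sep = "\r")
  idx <- match(paste(as.character(quality), age, sep = "\r"), key)
  miss <- which(is.na(idx))
  if (length(miss)) {
    if (!nearest_age) {
      ex <- miss[1L]
      stop("no stage distribution for (quality = ", quality[ex],
           ", age = ", age[ex], "); ", length(miss),
           " record(s) affected")
    }
    for (i in miss) {
      cand <- which(table$quality == as.character(quality[i]))
      if (!length(cand)) {
        stop("no stage distribution for quality = ", quality[i])
      }
      gap <- abs(table$age[cand] - age[i])
      best <- cand[gap == min(gap)]
      # ties broken toward the younger age
      idx[i] <- best[which.min(table$age[best])]
    }
  }
  idx
}

#' Impute developmental stages for unparasitized hosts
#'
#' Fills `stage_at_parasitism` for every unparasitized record by
#' inverse-CDF sampling from its (quality, age) cell of the
#' probability table; observed (parasitized) stages are never touched,
#' no other field is altered, and row order is preserved.
#'
#' @param records Exposure record data frame.
#' @param table A [estimate_stage_distribution()] table.
#' @param nearest_age If `TRUE`, a missing (quality, age) cell borrows
#'   the nearest age with data within the same quality (ties toward the
#'   younger age) instead of failing.
#' @return `records` with `stage_at_parasitism` complete.
#' @export
impute_stages <- function(records, table, nearest_age = FALSE) {
  stopifnot(inherits(table, "stage_distribution"),
            all(c("quality", "age_at_exposure", "parasitized",
                  "stage_at_parasitism") %in% names(records)))
  todo <- which(records$parasitized != 1L)
  if (!length(todo)) return(records)
  idx <- match_cells(table, records$quality[todo],
                     records$age_at_exposure[todo], nearest_age)
  cum <- t(apply(prob_matrix(table), 1L, cumsum))
  u <- runif(length(todo))
  # inverse CDF along the fixed stage order: count thresholds passed
  pick <- rowSums(u > cum[idx, , drop = FALSE] + 1e-15) + 1L
  records$stage_at_parasitism[todo] <- STAGE_LEVELS[pmin(pick, 6L)]
  records
}

#' Write / read a stage-distribution table
#'
#' Plain-text serialization (CSV) for inspection and reuse.
#'
#' @param table A `stage_distribution`.
#' @param path File path.
#' @return `write_stage_distribution()` returns `path` invisibly;
#'   `read_stage_distribution()` returns the table.
#' @export
write_stage_distribution <- function(table, path) {
  stopifnot(inherits(table, "stage_distribution"))
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stage_distribution
#' @export
read_stage_distribution <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("quality", "age", paste0("p_", STAGE_LEVELS), "n")
  if (!all(need %in% names(out)))
    stop("not a stage-distribution file: missing ",
         paste(setdiff(need, names(out)), collapse = ", "))
  out$quality <- as.character(out$quality)
  structure(out, class = c("stage_distribution", "data.frame"),
            provenance = path)
}
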