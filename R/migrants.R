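#' Directional aggregation of a sink-by-source migrant table
#'
#' Sums the off-diagonal cross-group blocks of a migrant table whose rows
#' are sink populations and whose columns are source populations, under a
#' two-group (e.g. species or ocean-basin) mapping, and reports the two
#' directional totals and the directional percentage
#' \code{100 * AtoB / (AtoB + BtoA)}.
#'
#' @param tab square numeric matrix, sinks x sources, with matching
#'   dimnames; the diagonal is ignored.
#' @param grouping named character vector mapping every population to one
#'   of exactly two group labels.
#' @return data.frame with one row per direction: \code{from}, \code{to},
#'   \code{total}, \code{percent}.
#' @export
aggregateDirectional <- function(tab, grouping) {
  stopifnot(is.matrix(tab), nrow(tab) == ncol(tab))
  pops <- rownames(tab)
  if (is.null(pops) || !identical(pops, colnames(tab)))
    stop("table needs identical row and column population names")
  if (!all(pops %in% names(grouping)))
    stop("grouping must cover all populations")
  groups <- unique(grouping[pops])
  if (length(groups) != 2) stop("grouping must define exactly two groups")
  g <- grouping[pops]
  blockSum <- function(fromGrp, toGrp) {
    sum(tab[g == toGrp, g == fromGrp, drop = FALSE], na.rm = TRUE)
  }
  tAB <- blockSum(groups[1], groups[2])
  tBA <- blockSum(groups[2], groups[1])
  data.frame(from = groups, to = rev(groups),
             total = c(tAB, tBA),
             percent = 100 * c(tAB, tBA) / (tAB + tBA),
             stringsAsFactors = FALSE)
}

#' Directional aggregation over a set of migrant tables
#'
#' Applies \code{\link{aggregateDirectional}} to each table (e.g. the
#' replicate SNP-subset estimates) and reports per-table totals and
#' percentages plus their ranges in each direction.
#'
#' @param tables named list of sink-by-source matrices.
#' @param grouping as in \code{\link{aggregateDirectional}}.
#' @return list with \code{perTable} (data.frame) and \code{range}
#'   (min/max of totals and percentages per direction).
#' @export
aggregateDirectionalSet <- function(tables, grouping) {
  stopifnot(length(tables) >= 1)
  per <- do.call(rbind, lapply(seq_along(tables), function(i) {
    d <- aggregateDirectional(tables[[i]], grouping)
    d$table <- if (!is.null(names(tables))) names(tables)[i] else i
    d
  }))
  dirs <- unique(per[, c("from", "to")])
  rng <- do.call(rbind, lapply(seq_len(nrow(dirs)), function(r) {
    sel <- per$from == dirs$from[r] & per$to == dirs$to[r]
    data.frame(from = dirs$from[r], to = dirs$to[r],
               minTotal = min(per$total[sel]),
               maxTotal = max(per$total[sel]),
               minPercent = min(per$percent[sel]),
               maxPercent = max(per$percent[sel]),
               stringsAsFactors = FALSE)
  }))
  list(perTable = per, range = rng)
}

#' Migrants per generation from mutation-scaled estimates
#'
#' The number of migrants per generation is the product of the
#' mutation-scaled population size Theta and the mutation-scaled
#' immigration rate M.
#'
#' @param theta mutation-scaled population size (>= 0).
#' @param M mutation-scaled immigration rate (>= 0).
#' @return \code{theta * M}, vectorized.
#' @examples
#' migrantsPerGeneration(0.5, 10)   # 5 migrants per generation
#' @export
migrantsPerGeneration <- function(theta, M) {
  if (any(theta < 0, na.rm = TRUE) || any(M < 0, na.rm = TRUE))
    stop("theta and M must be nonnegative")
  theta * M
}

#' Read / write a sink-by-source migrant table
#'
#' CSV layout: header row of source populations, first column of sink
#' populations; empty/NA diagonal allowed.
#'
#' @param path file path.
#' @return \code{readMigrantTable}: a numeric matrix with dimnames.
#' @export
readMigrantTable <- function(path) {
  d <- read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(d)
  storage.mode(m) <- "double"
  m
}

#' @rdname readMigrantTable
#' @param tab matrix to write.
#' @export
writeMigrantTable <- function(tab, path) {
  write.csv(as.data.frame(tab), path, row.names = TRUE)
  invisible(path)
}
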