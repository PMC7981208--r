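#' Write / read a flow field as NetCDF
#'
#' CF-style layout: dimensions \code{lon}, \code{lat}, \code{time};
#' variables \code{u}, \code{v} (m/s, per time stamp), \code{mask} (1 =
#' land) and \code{bathymetry} (m). \code{readFlowField} accepts a name
#' mapping for files written by other tools.
#'
#' @param field a \code{\link{FlowField-class}}.
#' @param path NetCDF file path.
#' @return \code{readFlowField}: a \code{FlowField}.
#' @export
writeFlowField <- function(field, path) {
  stopifnot(is(field, "FlowField"))
  dLon <- ncdf4::ncdim_def("lon", "degrees_east", field@lon)
  dLat <- ncdf4::ncdim_def("lat", "degrees_north", field@lat)
  dTime <- ncdf4::ncdim_def("time", "days", field@time,
                            unlim = FALSE)
  vU <- ncdf4::ncvar_def("u", "m s-1", list(dLon, dLat, dTime),
                         missval = 1e30, prec = "double")
  vV <- ncdf4::ncvar_def("v", "m s-1", list(dLon, dLat, dTime),
                         missval = 1e30, prec = "double")
  vM <- ncdf4::ncvar_def("mask", "1", list(dLon, dLat),
                         missval = -9L, prec = "integer")
  vB <- ncdf4::ncvar_def("bathymetry", "m", list(dLon, dLat),
                         missval = 1e30, prec = "double")
  nc <- ncdf4::nc_create(path, list(vU, vV, vM, vB))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, vU, field@u)
  ncdf4::ncvar_put(nc, vV, field@v)
  ncdf4::ncvar_put(nc, vM, field@mask + 0L)
  ncdf4::ncvar_put(nc, vB, field@bathy)
  invisible(path)
}

#' @rdname writeFlowField
#' @param vars named character vector mapping slots to variable names in
#'   the file (defaults match \code{writeFlowField}).
#' @export
readFlowField <- function(path, vars = c(u = "u", v = "v", mask = "mask",
                                         bathymetry = "bathymetry")) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  lon <- nc$dim$lon$vals
  lat <- nc$dim$lat$vals
  time <- if (!is.null(nc$dim$time)) nc$dim$time$vals else 0
  nt <- length(time)
  u <- array(ncdf4::ncvar_get(nc, vars[["u"]]),
             dim = c(length(lon), length(lat), nt))
  v <- array(ncdf4::ncvar_get(nc, vars[["v"]]),
             dim = c(length(lon), length(lat), nt))
  mask <- matrix(ncdf4::ncvar_get(nc, vars[["mask"]]) > 0,
                 length(lon), length(lat))
  bathy <- matrix(ncdf4::ncvar_get(nc, vars[["bathymetry"]]),
                  length(lon), length(lat))
  u[is.na(u)] <- 0; v[is.na(v)] <- 0
  new("FlowField", lon = as.numeric(lon), lat = as.numeric(lat),
      time = as.numeric(time), u = u, v = v, mask = mask, bathy = bathy)
}

#' Write / read a folded joint SFS in dadi-style text
#'
#' Three lines: dimensions plus the word \code{folded}, the flattened
#' entries (row-major over the (n1+1) x (n2+1) matrix), and the mask as
#' 0/1 in the same order.
#'
#' @param sfs a \code{\link{FoldedJSFS-class}}.
#' @param path file path.
#' @return \code{readDadiSFS}: a \code{FoldedJSFS}.
#' @export
writeDadiSFS <- function(sfs, path) {
  stopifnot(is(sfs, "FoldedJSFS"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(sfs@n1 + 1L, sfs@n2 + 1L, "folded"), con)
  writeLines(paste(as.vector(t(sfs@entries)), collapse = " "), con)
  writeLines(paste(as.integer(as.vector(t(sfs@mask))), collapse = " "),
             con)
  invisible(path)
}

#' @rdname writeDadiSFS
#' @export
readDadiSFS <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  hdr <- strsplit(trimws(ln[1]), "\\s+")[[1]]
  d1 <- as.integer(hdr[1]); d2 <- as.integer(hdr[2])
  ent <- as.numeric(strsplit(trimws(ln[2]), "\\s+")[[1]])
  msk <- as.integer(strsplit(trimws(ln[3]), "\\s+")[[1]])
  entries <- matrix(ent, d1, d2, byrow = TRUE)
  mask <- matrix(msk > 0, d1, d2, byrow = TRUE)
  new("FoldedJSFS", entries = entries, mask = mask,
      n1 = d1 - 1L, n2 = d2 - 1L, meta = list(source = path))
}

#' Write genotypes in Genepop format
#'
#' Two-digit allele coding (01 = reference, 02 = alternate, 0000 =
#' missing), one \code{Pop} block per population.
#'
#' @param gm a \code{\link{GenotypeMatrix-class}}.
#' @param path file path.
#' @param title first line of the file.
#' @export
writeGenepop <- function(gm, path, title = "seaconnect export") {
  stopifnot(is(gm, "GenotypeMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(gm@loci, con)
  G <- genotypes(gm)
  code <- function(g) {
    out <- rep("0000", length(g))
    out[!is.na(g) & g == 0] <- "0101"
    out[!is.na(g) & g == 1] <- "0102"
    out[!is.na(g) & g == 2] <- "0202"
    out
  }
  for (p in levels(populations(gm))) {
    writeLines("Pop", con)
    rows <- which(populations(gm) == p)
    for (i in rows)
      writeLines(paste0(p, "_", i, " ,  ",
                        paste(code(G[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname writeGenepop
#' @return \code{readGenepop}: a \code{GenotypeMatrix}.
#' @export
readGenepop <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  body <- ln[-1]
  isPop <- toupper(trimws(body)) == "POP"
  firstPop <- which(isPop)[1]
  loci <- trimws(body[seq_len(firstPop - 1)])
  loci <- unlist(strsplit(loci, ","))
  loci <- trimws(loci[nzchar(trimws(loci))])
  popId <- cumsum(isPop)
  rows <- which(!isPop & popId > 0)
  geno <- matrix(NA_integer_, length(rows), length(loci))
  pop <- character(length(rows))
  for (r in seq_along(rows)) {
    parts <- strsplit(body[rows[r]], ",")[[1]]
    al <- strsplit(trimws(parts[2]), "\\s+")[[1]]
    g <- rep(NA_integer_, length(al))
    g[al %in% c("0101", "001001")] <- 0L
    g[al %in% c("0102", "0201", "001002", "002001")] <- 1L
    g[al %in% c("0202", "002002")] <- 2L
    geno[r, ] <- g
    pop[r] <- paste0("pop", popId[rows[r]])
  }
  new("GenotypeMatrix", geno = geno, pop = factor(pop), loci = loci)
}

#' Write genotypes as a minimal VCF
#'
#' Diploid GT-only VCFv4.2 with placeholder coordinates (one pseudo-contig,
#' loci at consecutive positions), suitable for interchange with standard
#' tools.
#'
#' @param gm a \code{\link{GenotypeMatrix-class}}.
#' @param path file path.
#' @export
writeVcf <- function(gm, path) {
  stopifnot(is(gm, "GenotypeMatrix"))
  G <- genotypes(gm)
  ids <- paste0(as.character(populations(gm)), "_", seq_len(nrow(G)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", ids),
                     collapse = "\t")), con)
  gtCode <- c("0/0", "0/1", "1/1")
  for (l in seq_len(ncol(G))) {
    g <- G[, l]
    gt <- ifelse(is.na(g), "./.", gtCode[g + 1L])
    writeLines(paste(c("chr1", l, gm@loci[l], "A", "T", ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a VCF (GT field) with a population map
#'
#' Uses \pkg{vcfR} for parsing. The population map is a two-column
#' data.frame or tab/comma-separated file (individual, population).
#'
#' @param path VCF file path.
#' @param popMap data.frame with columns \code{individual},
#'   \code{population}, or a path to a two-column text file.
#' @return a \code{\link{GenotypeMatrix-class}}.
#' @export
readVcfGenotypes <- function(path, popMap) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("readVcfGenotypes requires the vcfR package")
  if (is.character(popMap)) {
    popMap <- read.table(popMap, header = TRUE, sep = "",
                         stringsAsFactors = FALSE)
    names(popMap)[1:2] <- c("individual", "population")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  cnt <- matrix(NA_integer_, ncol(gt), nrow(gt))
  clean <- gsub("\\|", "/", gt)
  cnt[t(clean == "0/0")] <- 0L
  cnt[t(clean == "0/1" | clean == "1/0")] <- 1L
  cnt[t(clean == "1/1")] <- 2L
  ind <- colnames(gt)
  pop <- popMap$population[match(ind, popMap$individual)]
  if (any(is.na(pop)))
    stop("population map is missing individuals: ",
         paste(ind[is.na(pop)], collapse = ", "))
  keep <- colSums(!is.na(cnt)) >= 1
  new("GenotypeMatrix", geno = cnt[, keep, drop = FALSE],
      pop = factor(pop),
      loci = rownames(gt)[keep])
}

#' Write a connectivity matrix or summary as CSV
#'
#' Header row and first column carry the site identifiers
#' (destination rows x source columns).
#'
#' @param x a \code{\link{ConnectivityMatrix-class}} or plain matrix.
#' @param path file path.
#' @export
writeConnectivity <- function(x, path) {
  m <- if (is(x, "ConnectivityMatrix")) connectivityEntries(x) else x
  write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' @rdname writeConnectivity
#' @return \code{readConnectivity}: numeric matrix with dimnames.
#' @export
readConnectivity <- function(path) {
  m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  storage.mode(m) <- "double"
  m
}
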