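#' Write genotypes in GENEPOP format
#'
#' Standard dialect: a title line, one locus name per line, groups
#' separated by \code{Pop} lines, one individual per row as
#' \code{id ,  <codes>} with 2- or 3-digit allele codes (3-digit
#' whenever any allele label exceeds 99) and \code{00..0} for missing.
#'
#' @param g \linkS4class{MultilocusGenotypes}.
#' @param path output file.
#' @param groups optional factor splitting individuals into populations
#'   (single Pop when omitted).
#' @param title title line.
#' @return invisibly, the path.
#' @export
writeGenepop <- function(g, path, groups = NULL,
                         title = "guanotype export") {
  digits <- if (max(c(g@a1, g@a2), na.rm = TRUE) > 99) 3L else 2L
  fmt <- function(x) ifelse(is.na(x), strrep("0", digits),
                            formatC(x, width = digits, flag = "0"))
  if (is.null(groups)) groups <- factor(rep("pop1", nInd(g)))
  groups <- factor(groups)
  ids <- sampleIds(g)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nInd(g)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(lociNames(g), con)
  for (v in levels(groups)) {
    writeLines("Pop", con)
    for (i in which(groups == v)) {
      codes <- paste0(fmt(g@a1[i, ]), fmt(g@a2[i, ]))
      writeLines(paste0(ids[i], " ,  ", paste(codes, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a GENEPOP file
#'
#' Accepts 2- and 3-digit allele coding, locus names one per line or
#' comma-separated on a single line, and all-zero codes as missing.
#'
#' @param path file path.
#' @return list with \code{genotypes} (a
#'   \linkS4class{MultilocusGenotypes}; metadata carries \code{group})
#'   and \code{groups} (factor).
#' @export
readGenepop <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  isPop <- toupper(trimws(lines)) == "POP"
  firstPop <- which(isPop)[1]
  if (is.na(firstPop) || firstPop < 3)
    stop("malformed GENEPOP file: no Pop separator after the locus list")
  lociLines <- lines[2:(firstPop - 1)]
  loci <- trimws(unlist(strsplit(lociLines, ",")))
  loci <- loci[nzchar(loci)]
  ids <- character(0)
  grp <- character(0)
  rows <- list()
  popIdx <- 0L
  for (i in firstPop:length(lines)) {
    if (isPop[i]) { popIdx <- popIdx + 1L; next }
    parts <- strsplit(lines[i], ",")[[1]]
    if (length(parts) < 2) stop("malformed individual line: ", lines[i])
    id <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = ",")),
                      "[[:space:]]+")[[1]]
    if (length(codes) != length(loci))
      stop("locus count mismatch for individual ", id)
    w <- unique(nchar(codes))
    if (length(w) != 1 || !(w %in% c(4L, 6L)))
      stop("odd-length allele codes for individual ", id)
    d <- w / 2
    a1 <- as.integer(substr(codes, 1, d))
    a2 <- as.integer(substr(codes, d + 1, w))
    a1[a1 == 0] <- NA_integer_
    a2[a2 == 0] <- NA_integer_
    miss <- is.na(a1) | is.na(a2)
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    ids <- c(ids, id)
    grp <- c(grp, paste0("pop", popIdx))
    rows[[length(rows) + 1L]] <- rbind(a1, a2)
  }
  a1 <- do.call(rbind, lapply(rows, function(r) r[1, ]))
  a2 <- do.call(rbind, lapply(rows, function(r) r[2, ]))
  g <- newGenotypes(a1, a2, loci,
                    meta = data.frame(group = grp), ids = ids)
  list(genotypes = g, groups = factor(grp))
}

#' Write a NEWHYBRIDS-format input file
#'
#' Lumped format: a count header, the locus names, then one row per
#' individual with both allele codes concatenated per locus and 0 for
#' missing, allowing cross-validation against the original software.
#'
#' @param g \linkS4class{MultilocusGenotypes}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeNewhybrids <- function(g, path) {
  digits <- if (max(c(g@a1, g@a2), na.rm = TRUE) > 99) 3L else 2L
  fmt <- function(x) ifelse(is.na(x), "0",
                            formatC(x, width = digits, flag = "0"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste("NumIndivs", nInd(g)),
               paste("NumLoci", nLoci(g)),
               paste("Digits", digits),
               "Format Lumped",
               paste("LocusNames", paste(lociNames(g), collapse = " "))),
             con)
  for (i in seq_len(nInd(g))) {
    codes <- ifelse(is.na(g@a1[i, ]), "0",
                    paste0(fmt(g@a1[i, ]), fmt(g@a2[i, ])))
    writeLines(paste(i, paste(codes, collapse = " ")), con)
  }
  invisible(path)
}
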