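#' Construct a 2x3 case-control genotype table
#'
#' Builds a validated [GenotypeTable-class] from case and control genotype
#' counts. Counts are ordered by copies of the minor allele A:
#' (aa, Aa, AA). The constructor never reorders columns; if the pooled
#' frequency of A exceeds 0.5, [minorAlleleFrequency()] warns that the
#' columns are likely mis-ordered.
#'
#' @param cases numeric(3), case counts (r0, r1, r2) for (aa, Aa, AA).
#' @param controls numeric(3), control counts (s0, s1, s2).
#' @param label optional character(1) identifier, e.g. a variant ID.
#' @param fractional logical; TRUE permits non-integer cells (tables of
#'   expected counts under a genetic model). Defaults to automatic
#'   detection: integer-valued cells give an integer-mode table.
#'
#' @return A [GenotypeTable-class] object.
#' @examples
#' tb <- genotypeTable(cases = c(1205, 624, 111),
#'                     controls = c(1608, 1121, 194),
#'                     label = "rs2398162")
#' nTotal(tb)  # 4863
#' @export
genotypeTable <- function(cases, controls, label = "", fractional = NULL) {
  cases <- as.numeric(cases)
  controls <- as.numeric(controls)
  if (is.null(fractional)) {
    cells <- c(cases, controls)
    fractional <- any(is.finite(cells) & abs(cells - round(cells)) > 1e-9)
  }
  new("GenotypeTable", cases = cases, controls = controls,
      label = as.character(label)[1L], fractional = isTRUE(fractional))
}

#' Accessors for GenotypeTable objects
#'
#' Margins are always recomputed from the cells: `genotypeTotals()` returns
#' the per-genotype totals n_i = r_i + s_i, `nCases()` the case total R,
#' `nControls()` the control total S and `nTotal()` N = R + S.
#'
#' @param x a [GenotypeTable-class].
#' @return Numeric counts, a character label, or a logical flag.
#' @name genotypeTable-accessors
#' @aliases caseCounts controlCounts genotypeTotals nCases nControls nTotal
#'   tableLabel isFractional
NULL

gtNames <- c("aa", "Aa", "AA")

#' @rdname genotypeTable-accessors
#' @export
setMethod("caseCounts", "GenotypeTable", function(x) {
  stats::setNames(x@cases, gtNames)
})

#' @rdname genotypeTable-accessors
#' @export
setMethod("controlCounts", "GenotypeTable", function(x) {
  stats::setNames(x@controls, gtNames)
})

#' @rdname genotypeTable-accessors
#' @export
setMethod("genotypeTotals", "GenotypeTable", function(x) {
  stats::setNames(x@cases + x@controls, gtNames)
})

#' @rdname genotypeTable-accessors
#' @export
setMethod("nCases", "GenotypeTable", function(x) sum(x@cases))

#' @rdname genotypeTable-accessors
#' @export
setMethod("nControls", "GenotypeTable", function(x) sum(x@controls))

#' @rdname genotypeTable-accessors
#' @export
setMethod("nTotal", "GenotypeTable", function(x) sum(x@cases) + sum(x@controls))

#' @rdname genotypeTable-accessors
#' @export
setMethod("tableLabel", "GenotypeTable", function(x) x@label)

#' @rdname genotypeTable-accessors
#' @export
setMethod("isFractional", "GenotypeTable", function(x) x@fractional)

setMethod("show", "GenotypeTable", function(object) {
  lbl <- if (nzchar(object@label)) paste0(" '", object@label, "'") else ""
  mode <- if (object@fractional) "fractional" else "integer"
  cat(sprintf("GenotypeTable%s (%s counts)\n", lbl, mode))
  m <- rbind(cases = object@cases, controls = object@controls)
  colnames(m) <- gtNames
  m <- cbind(m, total = rowSums(m))
  m <- rbind(m, total = colSums(m))
  print(m)
  invisible(NULL)
})

#' Pooled minor allele frequency of a genotype table
#'
#' Frequency of allele A pooled over cases and controls,
#' (n1 + 2 n2) / (2 N). A value above 0.5 triggers a warning: the package
#' convention orders genotype columns by minor-allele count (aa, Aa, AA),
#' so a pooled frequency above one half suggests the columns were supplied
#' in the reverse order. Applied to a [GeneticModel-class], returns the
#' model's population minor allele frequency q.
#'
#' @param x a [GenotypeTable-class] or [GeneticModel-class].
#' @param ... unused.
#' @return A frequency in [0, 1].
#' @examples
#' tb <- genotypeTable(c(1205, 624, 111), c(1608, 1121, 194))
#' minorAlleleFrequency(tb)  # about 0.2421
#' @export
setMethod("minorAlleleFrequency", "GenotypeTable", function(x, ...) {
  n <- x@cases + x@controls
  N <- sum(n)
  p <- (n[2L] + 2 * n[3L]) / (2 * N)
  if (p > 0.5)
    warning("pooled frequency of allele A exceeds 0.5; genotype columns ",
            "are likely ordered (AA, Aa, aa) instead of (aa, Aa, AA)")
  unname(p)
})

#' Read a genotype table from a TSV file
#'
#' Expects a tab-separated file with a header row naming the genotype
#' columns and two data rows labelled `cases` and `controls`:
#' ```
#' genotype  aa   Aa   AA
#' cases     r0   r1   r2
#' controls  s0   s1   s2
#' ```
#' Fractional cell values are accepted and yield a fractional-mode table.
#'
#' @param path path to the TSV file.
#' @param label table label; defaults to the file name without extension.
#' @return A [GenotypeTable-class].
#' @seealso [writeGenotypeTable()] for the inverse; the round trip is
#'   lossless.
#' @export
readGenotypeTable <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) != 4L)
    stop("malformed table in '", path, "': expected 4 tab-separated columns ",
         "(row label + 3 genotypes), found ", ncol(df))
  rows <- tolower(trimws(as.character(df[[1L]])))
  ic <- match("cases", rows)
  io <- match("controls", rows)
  if (is.na(ic) || is.na(io))
    stop("malformed table in '", path,
         "': need one row labelled 'cases' and one labelled 'controls'")
  num <- function(row, what) {
    v <- suppressWarnings(as.numeric(unlist(df[row, 2:4])))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("non-numeric count in '", path, "', row '", what, "', column '",
           names(df)[1L + bad[1L]], "'")
    if (any(v < 0))
      stop("negative count in '", path, "', row '", what, "'")
    v
  }
  if (is.null(label))
    label <- sub("\\.[^.]*$", "", basename(path))
  genotypeTable(num(ic, "cases"), num(io, "controls"), label = label)
}

#' Write a genotype table to a TSV file
#'
#' Writes the dialect read by [readGenotypeTable()]. Cell values are
#' written at full precision (`format(..., digits = 17)` for fractional
#' tables), so a read/write round trip is lossless.
#'
#' @param x a [GenotypeTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGenotypeTable <- function(x, path) {
  stopifnot(is(x, "GenotypeTable"))
  fmt <- function(v) {
    if (x@fractional) vapply(v, format, "", digits = 17L) else format(v)
  }
  lines <- c(
    paste(c("genotype", gtNames), collapse = "\t"),
    paste(c("cases", fmt(x@cases)), collapse = "\t"),
    paste(c("controls", fmt(x@controls)), collapse = "\t")
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Bundled example genotype tables
#'
#' Returns one of the genotype tables shipped with the package, or lists
#' the available names. Currently bundled: `rs2398162`, the hypertension
#' variant from the Wellcome Trust Case Control Consortium study with
#' 1940 cases (1205, 624, 111) and 2923 controls (1608, 1121, 194),
#' for which the minor allele was suggested to act dominantly.
#'
#' @param name fixture name, or `NULL` to list available fixtures.
#' @return A [GenotypeTable-class], or a character vector of names.
#' @examples
#' exampleTable()             # available names
#' tb <- exampleTable("rs2398162")
#' @export
exampleTable <- function(name = NULL) {
  dir <- system.file("extdata", package = "genotrend")
  avail <- sub("\\.tsv$", "", list.files(dir, pattern = "\\.tsv$"))
  if (is.null(name)) return(avail)
  if (!name %in% avail)
    stop("unknown fixture '", name, "'; available: ",
         paste(avail, collapse = ", "))
  readGenotypeTable(file.path(dir, paste0(name, ".tsv")), label = name)
}
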