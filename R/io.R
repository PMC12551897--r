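#' Read p-values from a text or CSV file
#'
#' Accepts either a plain text file with one p-value per line or a CSV
#' with a header; for CSVs the column named `column` (default: the first
#' of `"pvalue"`, `"p"`, or the first numeric column) is extracted in
#' file order. Values outside \[0, 1\] or unparseable rows raise an error
#' naming the offending line.
#'
#' @param path file to read.
#' @param column optional CSV column name.
#' @return numeric vector of p-values.
#' @export
read_pvalues <- function(path, column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty input file: ", path, call. = FALSE)
  looks_csv <- grepl(",", lines[1L]) ||
    is.na(suppressWarnings(as.numeric(trimws(lines[1L]))))
  if (looks_csv) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (is.null(column)) {
      hits <- intersect(c("pvalue", "p"), tolower(names(d)))
      column <- if (length(hits)) names(d)[match(hits[1L], tolower(names(d)))]
                else names(d)[which(vapply(d, is.numeric, TRUE))[1L]]
      if (is.null(column) || is.na(column)) {
        stop("no numeric p-value column found in ", path, call. = FALSE)
      }
    }
    if (!column %in% names(d)) {
      stop("column '", column, "' not found in ", path, call. = FALSE)
    }
    p <- d[[column]]
  } else {
    p <- suppressWarnings(as.numeric(trimws(lines)))
    bad <- which(is.na(p))
    if (length(bad)) {
      stop("cannot parse p-value on line ", bad[1L], ": '",
           lines[bad[1L]], "'", call. = FALSE)
    }
  }
  bad <- which(is.na(p) | p < 0 | p > 1)
  if (length(bad)) {
    stop("p-value out of [0, 1] at position ", bad[1L], ": ",
         p[bad[1L]], call. = FALSE)
  }
  p
}

#' Write p-values to a CSV file
#'
#' One column named `pvalue`; [read_pvalues()] on the result round-trips
#' the vector exactly (values are written with full precision).
#'
#' @param p numeric vector of p-values.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_pvalues <- function(p, path) {
  df <- data.frame(pvalue = format(p, digits = 17, scientific = TRUE,
                                   trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a combination result to JSON or CSV
#'
#' @param result a `"combination_result"` or the data frame returned by
#'   `combine_pvalues(..., method = "all")`.
#' @param path destination file.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (inherits(result, "combination_result")) {
    result <- data.frame(method = result$method, m = result$m,
                         statistic = result$statistic,
                         combined_p = result$combined_p,
                         stringsAsFactors = FALSE)
  }
  if (format == "json") {
    jsonlite::write_json(result, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(result, path, row.names = FALSE)
  }
  invisible(path)
}

#' Combined p-values for the packaged meta-analysis examples
#'
#' Two small GWAS meta-analyses of SNP-disorder association p-values ship
#' with the package (`inst/extdata/meta_analysis_1.csv`, six studies of
#' one SNP; `meta_analysis_2.csv`, five studies of another). This
#' function loads both sets and combines each with the CCT, Fisher and
#' MinP tests (equal weights).
#'
#' @return data frame with columns `study`, `method`, `m`, `statistic`,
#'   `combined_p`.
#' @examples
#' run_worked_examples()
#' @export
run_worked_examples <- function() {
  files <- c(meta_analysis_1 = "meta_analysis_1.csv",
             meta_analysis_2 = "meta_analysis_2.csv")
  out <- lapply(names(files), function(nm) {
    path <- system.file("extdata", files[[nm]], package = "cctcount",
                        mustWork = TRUE)
    res <- combine_pvalues(read_pvalues(path), method = "all")
    cbind(study = nm, res, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run manifest for reproducible command-line output
#'
#' Records the configuration, seed, timestamp, package version and md5
#' checksum of every output file, so a run can be replayed and verified
#' bit for bit.
#'
#' @param config list of configuration values to echo.
#' @param seed integer seed used for the run.
#' @param files character vector of output files to checksum.
#' @param path destination JSON file; `NULL` returns the manifest without
#'   writing.
#' @return the manifest, invisibly (a list).
#' @export
run_manifest <- function(config, seed, files, path = NULL) {
  manifest <- list(
    package = "cctcount",
    version = as.character(utils::packageVersion("cctcount")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    outputs = lapply(files[file.exists(files)], function(f) {
      list(file = f, md5 = unname(tools::md5sum(f)))
    })
  )
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(manifest)
}
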