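#' Read biallelic SNP records from a VCF file
#'
#' Parses a VCF 4.x file (FreeBayes dialect) into a data frame of per-site,
#' per-alternate-allele records. Depth and per-allele observation counts are
#' taken from the INFO fields `DP`, `AO` and `RO`; when these are absent the
#' per-sample FORMAT field `AD` (allele depths) of the first sample is used
#' instead. Multi-allelic sites yield one record per alternate allele, with
#' `n_alts_at_site` recording how many alternates were observed so that
#' downstream filters can enforce biallelism. Indels (REF or ALT longer than
#' one base) are flagged via `is_indel`, not dropped.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param time_index Zero-based index of the time point this VCF was called
#'   from; stored on every record.
#' @return A data frame with one row per (site, alternate allele):
#'   `genome_id`, `position`, `ref`, `alt`, `time_index`, `qual`, `depth`,
#'   `alt_count`, `ref_count`, `n_alts_at_site`, `is_indel`.
#' @export
read_snp_vcf <- function(path, time_index = 0L) {
  if (!file.exists(path)) {
    stop("cannot read VCF: file not found: ", path)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  empty <- data.frame(
    genome_id = character(), position = integer(), ref = character(),
    alt = character(), time_index = integer(), qual = numeric(),
    depth = integer(), alt_count = integer(), ref_count = integer(),
    n_alts_at_site = integer(), is_indel = logical(),
    stringsAsFactors = FALSE
  )
  if (is.null(fix) || nrow(vcf@fix) == 0L) {
    return(empty)
  }
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)

  dp <- suppressWarnings(as.integer(vcfR::extract.info(vcf, "DP")))
  ao_raw <- vcfR::extract.info(vcf, "AO")
  ro <- suppressWarnings(as.integer(vcfR::extract.info(vcf, "RO")))

  use_info <- !all(is.na(dp)) && !all(is.na(ao_raw)) && !all(is.na(ro))
  if (!use_info) {
    # fall back to FORMAT AD of the first sample: "refDepth,altDepth[,...]"
    gt <- vcf@gt
    if (is.null(gt) || ncol(gt) < 2L) {
      stop("VCF format error: no INFO DP/AO/RO and no FORMAT field ",
           "to fall back on (need AD)")
    }
    ad <- tryCatch(vcfR::extract.gt(vcf, element = "AD")[, 1L],
                   error = function(e) NULL)
    if (is.null(ad) || all(is.na(ad))) {
      stop("VCF format error: missing allele count field (INFO AO/RO or ",
           "FORMAT AD)")
    }
    ad_split <- strsplit(ad, ",", fixed = TRUE)
    ro <- vapply(ad_split, function(x) suppressWarnings(as.integer(x[1L])),
                 integer(1))
    ao_raw <- vapply(ad_split, function(x) paste(x[-1L], collapse = ","),
                     character(1))
    if (all(is.na(dp))) {
      dp_fmt <- tryCatch(vcfR::extract.gt(vcf, element = "DP")[, 1L],
                         error = function(e) NULL)
      if (is.null(dp_fmt)) {
        dp <- ro + vapply(ad_split, function(x) {
          sum(suppressWarnings(as.integer(x[-1L])), na.rm = TRUE)
        }, integer(1))
      } else {
        dp <- suppressWarnings(as.integer(dp_fmt))
      }
    }
  }
  if (all(is.na(dp))) stop("VCF format error: missing depth field DP")

  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  alt_flat <- unlist(alts, use.names = FALSE)
  ao_split <- strsplit(ifelse(is.na(ao_raw), "", ao_raw), ",", fixed = TRUE)
  ao_flat <- suppressWarnings(as.integer(unlist(lapply(
    seq_along(ao_split),
    function(i) {
      x <- ao_split[[i]]
      length(x) <- n_alt[i]  # pad with NA if fewer counts than alts
      x
    }
  ), use.names = FALSE)))

  out <- data.frame(
    genome_id = fix$CHROM[idx],
    position = as.integer(fix$POS[idx]),
    ref = fix$REF[idx],
    alt = alt_flat,
    time_index = as.integer(time_index),
    qual = suppressWarnings(as.numeric(fix$QUAL[idx])),
    depth = dp[idx],
    alt_count = ao_flat,
    ref_count = ro[idx],
    n_alts_at_site = n_alt[idx],
    stringsAsFactors = FALSE
  )
  out$is_indel <- nchar(out$ref) != 1L | nchar(out$alt) != 1L
  rownames(out) <- NULL
  out
}

#' Write SNP records to a minimal VCF file
#'
#' Emits a VCF 4.2 file in the same dialect [read_snp_vcf()] expects
#' (INFO `DP`, `AO`, `RO`), so synthetic observations can be round-tripped
#' through the standard format.
#'
#' @param records Data frame as returned by [read_snp_vcf()] (columns
#'   `genome_id`, `position`, `ref`, `alt`, `qual`, `depth`, `alt_count`,
#'   `ref_count`). Rows sharing `genome_id`+`position` are merged into one
#'   multi-allelic line.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(records, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=AO,Number=A,Type=Integer,Description=\"Alternate allele observations\">",
    "##INFO=<ID=RO,Number=1,Type=Integer,Description=\"Reference allele observations\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  lines <- character(0)
  if (nrow(records) > 0L) {
    key <- paste(records$genome_id, records$position, sep = "\r")
    lines <- vapply(split(seq_len(nrow(records)), key)[unique(key)],
      function(ii) {
        r <- records[ii, , drop = FALSE]
        sprintf("%s\t%d\t.\t%s\t%s\t%.2f\t.\tDP=%d;AO=%s;RO=%d",
                r$genome_id[1L], r$position[1L], r$ref[1L],
                paste(r$alt, collapse = ","), r$qual[1L], r$depth[1L],
                paste(r$alt_count, collapse = ","), r$ref_count[1L])
      }, character(1))
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Construct a taxa-by-time relative abundance table
#'
#' @param values Numeric matrix, taxa in rows, time points in columns; every
#'   column must sum to 1 within `tol` (columns are renormalized to exactly 1).
#' @param taxa Data frame with one row per taxon; must contain `taxon_id` and
#'   may carry lineage columns (`family`, `genus`, `species`, `strain`).
#' @param times Numeric vector of generation coordinates, one per column.
#' @param tol Allowed deviation of column sums from 1 before erroring.
#' @return An object of class `abundance_table`: a list with `values`,
#'   `taxa`, `times`.
#' @export
abundance_table <- function(values, taxa, times = seq_len(ncol(values)) - 1,
                            tol = 1e-3) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("abundance table contains negative values")
  if (anyDuplicated(taxa$taxon_id)) {
    stop("duplicate taxon id: ",
         paste(unique(taxa$taxon_id[duplicated(taxa$taxon_id)]),
               collapse = ", "))
  }
  if (nrow(taxa) != nrow(values)) stop("taxa/values row mismatch")
  if (length(times) != ncol(values)) stop("times/values column mismatch")
  sums <- colSums(values)
  if (any(abs(sums - 1) > tol)) {
    stop(sprintf("column sums deviate from 1 beyond tolerance %g (max %g)",
                 tol, max(abs(sums - 1))))
  }
  values <- sweep(values, 2L, sums, "/")
  rownames(values) <- taxa$taxon_id
  structure(list(values = values, taxa = taxa, times = as.numeric(times)),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d taxa x %d time points\n",
              nrow(x$values), ncol(x$values)))
  cat("generations:", paste(signif(x$times, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Read a taxa-by-time relative abundance TSV
#'
#' Expects a `taxon_id` column, optional lineage columns (`family`, `genus`,
#' `species`, `strain`), and one numeric column per time point named
#' `g<generations>` (e.g. `g23.1`) or plain numbers. Columns must sum to 1
#' within `tol` and are renormalized to exactly 1.
#'
#' @param path TSV path.
#' @param tol Column-sum tolerance (default 1e-3).
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path, tol = 1e-3) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"taxon_id" %in% names(df)) stop("abundance TSV needs a taxon_id column")
  lineage_cols <- intersect(c("family", "genus", "species", "strain"),
                            names(df))
  time_cols <- setdiff(names(df), c("taxon_id", lineage_cols))
  times <- suppressWarnings(as.numeric(sub("^g", "", time_cols)))
  if (any(is.na(times))) {
    stop("unparseable time columns: ",
         paste(time_cols[is.na(times)], collapse = ", "))
  }
  values <- as.matrix(df[, time_cols, drop = FALSE])
  abundance_table(values, df[, c("taxon_id", lineage_cols), drop = FALSE],
                  times = times, tol = tol)
}

#' Write an abundance table to TSV
#'
#' Columns: `taxon_id`, lineage columns, then one `g<generations>` column per
#' time point. Round-trips through [read_abundance_table()] to 1e-9.
#'
#' @param x An [abundance_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path) {
  stopifnot(inherits(x, "abundance_table"))
  vals <- as.data.frame(x$values)
  names(vals) <- paste0("g", format(x$times, trim = TRUE, digits = 15))
  out <- cbind(x$taxa, vals)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a named set of result tables to a directory
#'
#' Each element of `tables` (a data frame or an `abundance_table`) is written
#' as `<name>.tsv` with a deterministic column order (as given). Refuses to
#' clobber existing files unless `overwrite = TRUE`.
#'
#' @param tables Named list of data frames and/or `abundance_table`s.
#' @param out_dir Output directory (created if absent).
#' @param overwrite Allow replacing existing files.
#' @return Manifest data frame with `name`, `file`, `rows`.
#' @export
write_results <- function(tables, out_dir, overwrite = FALSE) {
  if (length(tables) && (is.null(names(tables)) || any(names(tables) == ""))) {
    stop("every table must be named")
  }
  if (anyDuplicated(names(tables))) {
    stop("duplicate table name: ",
         paste(unique(names(tables)[duplicated(names(tables))]),
               collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(name = character(), file = character(),
                         rows = integer(), stringsAsFactors = FALSE)
  for (nm in names(tables)) {
    file <- file.path(out_dir, paste0(nm, ".tsv"))
    if (file.exists(file) && !overwrite) {
      stop("refusing to overwrite existing file: ", file)
    }
    x <- tables[[nm]]
    if (inherits(x, "abundance_table")) {
      write_abundance_table(x, file)
      nrows <- nrow(x$values)
    } else {
      utils::write.table(as.data.frame(x), file, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      nrows <- nrow(x)
    }
    manifest <- rbind(manifest,
                      data.frame(name = nm, file = file, rows = nrows,
                                 stringsAsFactors = FALSE))
  }
  manifest
}
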