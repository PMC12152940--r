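#' Read dose-response measurements from a long-format CSV
#'
#' Expected header: `molecule_id, concentration, response` (one measurement
#' per row, concentrations in a single unit per file). An optional
#' `replicate_id` column is carried through. Returns one
#' [dose_response_set()] per molecule; molecules without any measurement
#' row cannot occur in this format, but all-NA molecules are dropped with
#' a warning.
#'
#' @param path CSV file path.
#' @param direction Assay direction applied to every molecule.
#' @return Named list of `dose_response_set` objects.
#' @export
read_dose_response_csv <- function(path,
                                   direction = c("efficacy", "inhibition")) {
  direction <- match.arg(direction)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("molecule_id", "concentration", "response")
  if (!all(need %in% names(df)))
    stop("missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  line <- seq_len(nrow(df)) + 1L # header is line 1
  df$concentration <- suppressWarnings(as.numeric(df$concentration))
  df$response <- suppressWarnings(as.numeric(df$response))
  bad <- which(!is.finite(df$concentration) | !is.finite(df$response))
  if (length(bad) > 0)
    stop("malformed rows (non-numeric or missing values) at line(s) ",
         paste(utils::head(line[bad], 10), collapse = ", "))
  nonpos <- which(df$concentration <= 0)
  if (length(nonpos) > 0)
    stop("nonpositive concentration at line(s) ",
         paste(utils::head(line[nonpos], 10), collapse = ", "))
  keep <- !is.na(df$molecule_id) & df$molecule_id != ""
  if (!all(keep)) {
    warning(sum(!keep), " rows without a molecule id removed")
    df <- df[keep, , drop = FALSE]
  }
  ids <- unique(df$molecule_id)
  sets <- lapply(ids, function(id) {
    rows <- df[df$molecule_id == id, , drop = FALSE]
    dose_response_set(id, rows$concentration, rows$response,
                      direction = direction,
                      replicate_id = rows$replicate_id)
  })
  names(sets) <- ids
  sets
}

#' Write dose-response sets to the canonical long-format CSV
#'
#' @param sets List of [dose_response_set()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dose_response_csv <- function(sets, path) {
  df <- do.call(rbind, lapply(sets, function(s)
    data.frame(molecule_id = s$molecule_id,
               concentration = s$measurements$concentration,
               response = s$measurements$response,
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a binary feature matrix CSV
#'
#' First column `molecule_id`, remaining columns 0/1 features.
#'
#' @param path CSV path.
#' @return `read_feature_csv`: numeric matrix with molecule-id rownames.
#' @export
read_feature_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "molecule_id")
    stop("first column must be 'molecule_id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!all(m %in% c(0, 1))) stop("features must be 0/1")
  rownames(m) <- df$molecule_id
  m
}

#' @rdname read_feature_csv
#' @param features 0/1 matrix with molecule-id rownames.
#' @export
write_feature_csv <- function(features, path) {
  df <- data.frame(molecule_id = rownames(features), features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a quality table
#'
#' Serialized as a single CSV: molecule_id, target, quality, then the
#' feature columns.
#'
#' @param table A [quality_table()].
#' @param path CSV path.
#' @export
write_quality_table_csv <- function(table, path) {
  df <- data.frame(molecule_id = table$molecule_id, target = table$target,
                   quality = table$quality, table$features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_quality_table_csv
#' @export
read_quality_table_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  feats <- as.matrix(df[, -(1:3), drop = FALSE])
  rownames(feats) <- df$molecule_id
  structure(list(molecule_id = df$molecule_id, features = feats,
                 target = df$target, quality = df$quality),
            class = "quality_table")
}

#' Morgan fingerprints from SMILES
#'
#' Featurization hook producing 1024-bit circular (Morgan/ECFP) fingerprint
#' rows, radius 2, via the RDKit toolkit (invoked through the `python`
#' interpreter on the PATH). Unparseable SMILES raise an error listing the
#' offenders rather than being silently dropped. The hook is optional:
#' every pipeline entry point also accepts a precomputed 0/1 feature
#' matrix.
#'
#' @param smiles Character vector of SMILES strings (names, if present,
#'   become rownames).
#' @param n_bits Fingerprint length (default 1024).
#' @param radius Circular radius (default 2).
#' @param python Python executable with RDKit available.
#' @return 0/1 matrix with one row per input.
#' @export
featurize_smiles <- function(smiles, n_bits = 1024, radius = 2,
                             python = "python") {
  if (length(smiles) == 0)
    return(matrix(numeric(0), 0, n_bits))
  infile <- tempfile(fileext = ".txt")
  outfile <- tempfile(fileext = ".txt")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  writeLines(smiles, infile)
  script <- sprintf(paste(
    "import sys",
    "from rdkit import Chem",
    "from rdkit.Chem import rdFingerprintGenerator",
    "gen = rdFingerprintGenerator.GetMorganGenerator(radius=%d, fpSize=%d)",
    "bad = []",
    "rows = []",
    "with open(sys.argv[1]) as fh:",
    "    for i, line in enumerate(fh):",
    "        m = Chem.MolFromSmiles(line.strip())",
    "        if m is None:",
    "            bad.append(str(i + 1)); rows.append(None); continue",
    "        rows.append(gen.GetFingerprint(m).ToBitString())",
    "if bad:",
    "    sys.stderr.write('unparseable:' + ','.join(bad)); sys.exit(3)",
    "with open(sys.argv[2], 'w') as out:",
    "    out.write('\\n'.join(rows))",
    sep = "\n"), radius, n_bits)
  res <- suppressWarnings(system2(python, c("-c", shQuote(script),
                                            shQuote(infile), shQuote(outfile)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    badline <- grep("^unparseable:", res, value = TRUE)
    if (length(badline) > 0) {
      idx <- as.integer(strsplit(sub("^unparseable:", "", badline), ",")[[1]])
      stop("unparseable SMILES at position(s) ",
           paste(idx, collapse = ", "), ": ",
           paste(utils::head(smiles[idx], 10), collapse = ", "))
    }
    stop("fingerprint generation failed: ", paste(res, collapse = "\n"))
  }
  bits <- readLines(outfile, warn = FALSE)
  m <- t(vapply(bits, function(b)
    as.numeric(strsplit(b, "")[[1]]), numeric(n_bits)))
  dimnames(m) <- list(names(smiles), sprintf("f%04d", seq_len(n_bits)))
  m
}

#' Serialize an evaluation report
#'
#' Pairs go to `<stem>_pairs.csv`, summary statistics (RMSE, bootstrap SD,
#' pair count, model family) to `<stem>_summary.json`.
#'
#' @param report An [evaluate_on_dose_response()] report.
#' @param stem Output path stem.
#' @param rmse_sd Optional precomputed bootstrap SD to include.
#' @return The two paths, invisibly.
#' @export
write_evaluation_report <- function(report, stem, rmse_sd = NULL) {
  pairs_path <- paste0(stem, "_pairs.csv")
  json_path <- paste0(stem, "_summary.json")
  utils::write.csv(report$pairs, pairs_path, row.names = FALSE)
  jsonlite::write_json(list(model_family = report$model_family,
                            rmse = report$rmse, rmse_sd = rmse_sd,
                            n_pairs = report$n_pairs),
                       json_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(pairs_path, json_path))
}
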