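#' @importFrom utils read.csv write.csv
NULL

# Canonical internal column names and the default header spellings used in the
# "Transformations in PubChem - Full Dataset" CSV deposits. Matching against
# source headers is case- and punctuation-insensitive; a user-supplied
# column_map (canonical -> source header) overrides these defaults.
.compound_columns <- list(
  cid         = c("CID", "cid", "CompoundCID"),
  smiles      = c("SMILES", "CanonicalSMILES", "IsomericSMILES"),
  inchi       = c("InChI", "INCHI"),
  inchikey    = c("InChIKey", "INCHIKEY"),
  ikfb        = c("IKFB", "InChIKeyFirstBlock"),
  formula     = c("MolecularFormula", "Formula", "MolFormula"),
  exact_mass  = c("ExactMass", "MonoisotopicMass", "ExactMW"),
  xlogp       = c("XlogP", "XLogP", "XLOGP"),
  iupac_name  = c("IUPACName", "IUPAC_Name"),
  title       = c("Title", "PubChemTitle")
)

.reaction_columns <- list(
  predecessor_cid      = c("predecessorcid", "predecessor_cid", "PredecessorCID"),
  successor_cid        = c("successorcid", "successor_cid", "SuccessorCID"),
  predecessor_name     = c("predecessor", "predecessorname", "predecessor_name"),
  successor_name       = c("successor", "successorname", "successor_name"),
  reaction_smiles      = c("ReactionSMILES", "reactionsmiles"),
  desc_reaction_smiles = c("DescReactionSMILES", "descreactionsmiles"),
  biosystem            = c("biosystem", "Biosystem"),
  enzyme               = c("enzyme", "Enzyme"),
  transformation       = c("transformation", "Transformation"),
  mass_diff            = c("MassDiff", "massdiff", "mass_diff"),
  xlogp_diff           = c("XlogPDiff", "xlogpdiff", "xlogp_diff"),
  datasetref           = c("datasetref", "DatasetRef"),
  datasetdoi           = c("datasetdoi", "DatasetDOI"),
  evidenceref          = c("evidenceref", "EvidenceRef"),
  evidencedoi          = c("evidencedoi", "EvidenceDOI"),
  sourcecommentfull    = c("sourcecommentfull", "SourceCommentFull"),
  sourcecomment        = c("sourcecomment", "SourceComment")
)

.norm_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

# Resolve canonical -> actual header for one table. column_map entries
# (canonical name -> literal source header) take precedence over defaults.
.resolve_columns <- function(header, defaults, column_map = NULL) {
  out <- stats::setNames(rep(NA_character_, length(defaults)), names(defaults))
  nh <- .norm_header(header)
  for (canon in names(defaults)) {
    cands <- defaults[[canon]]
    if (!is.null(column_map) && canon %in% names(column_map)) {
      cands <- column_map[[canon]]
    }
    hit <- which(nh %in% .norm_header(cands))
    if (length(hit)) out[[canon]] <- header[hit[1L]]
  }
  out
}

.read_raw_csv <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  utils::read.csv(path, colClasses = "character", check.names = FALSE,
                  stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                  na.strings = character(0))
}

.trim_all <- function(df) {
  for (j in seq_along(df)) df[[j]] <- trimws(df[[j]])
  df
}

.parse_cid <- function(x) {
  x <- trimws(x)
  out <- suppressWarnings(as.integer(x))
  out[!is.na(out) & out <= 0L] <- NA_integer_
  # reject non-numeric leftovers like "12a" that as.integer would NA anyway
  out
}

.parse_num <- function(x) {
  x[x == ""] <- NA_character_
  suppressWarnings(as.numeric(x))
}

.na_if_empty <- function(x) {
  x[!nzchar(x)] <- NA_character_
  x
}

#' Read a compound-level table
#'
#' Reads the compound information CSV (one row per compound, keyed by PubChem
#' CID) into a data frame with canonical column names: `cid`, `smiles`,
#' `inchi`, `inchikey`, `ikfb`, `formula`, `exact_mass`, `xlogp`,
#' `iupac_name`, `title`. Columns not recognised as part of the schema are
#' preserved verbatim after the canonical ones. Rows whose CID cannot be
#' parsed as a positive integer are skipped and reported in the `"skipped"`
#' attribute rather than aborting the load.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param column_map Optional named list mapping canonical column names
#'   (e.g. `cid`) to the literal header used in the file.
#' @return A data frame of compounds with attribute `skipped`, a data frame
#'   of `(row, reason)` for rows dropped during parsing.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("CID,SMILES,ExactMass", "2256,CCO,46.0419"), f)
#' read_compound_table(f)
#' @export
read_compound_table <- function(path, column_map = NULL) {
  raw <- .trim_all(.read_raw_csv(path))
  cols <- .resolve_columns(names(raw), .compound_columns, column_map)
  if (is.na(cols[["cid"]])) {
    stop("compound table schema error: no CID column found.\n",
         "  headers present: ", paste(names(raw), collapse = ", "), "\n",
         "  expected one of: ", paste(.compound_columns$cid, collapse = ", "),
         " (or supply column_map)", call. = FALSE)
  }
  n <- nrow(raw)
  get <- function(canon) {
    src <- cols[[canon]]
    if (is.na(src)) rep(NA_character_, n) else .na_if_empty(raw[[src]])
  }
  cid <- .parse_cid(if (n) raw[[cols[["cid"]]]] else character(0))
  out <- data.frame(
    cid        = cid,
    smiles     = get("smiles"),
    inchi      = get("inchi"),
    inchikey   = get("inchikey"),
    ikfb       = get("ikfb"),
    formula    = get("formula"),
    exact_mass = .parse_num(get("exact_mass")),
    xlogp      = .parse_num(get("xlogp")),
    iupac_name = get("iupac_name"),
    title      = get("title"),
    stringsAsFactors = FALSE
  )
  extra <- setdiff(names(raw), stats::na.omit(unname(cols)))
  for (e in extra) out[[e]] <- raw[[e]]

  bad <- which(is.na(cid))
  skipped <- data.frame(row = bad,
                        reason = rep("unparseable CID", length(bad)),
                        stringsAsFactors = FALSE)
  if (length(bad)) out <- out[-bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Read a reaction-level table
#'
#' Reads the reaction CSV (one row per directed predecessor -> successor
#' transformation) into a data frame with canonical column names
#' (`predecessor_cid`, `successor_cid`, `predecessor_name`, `successor_name`,
#' `reaction_smiles`, `desc_reaction_smiles`, `biosystem`, `enzyme`,
#' `transformation`, `mass_diff`, `xlogp_diff`, `datasetref`, `datasetdoi`,
#' `evidenceref`, `evidencedoi`, `sourcecommentfull`, `sourcecomment`).
#' Duplicate rows are retained verbatim: deduplication is a query-time
#' concern, and parallel reactions carry distinct evidence. Rows whose
#' endpoint CIDs cannot be parsed are skipped and reported via the
#' `"skipped"` attribute.
#'
#' @inheritParams read_compound_table
#' @return A data frame of reactions with attribute `skipped`.
#' @export
read_reaction_table <- function(path, column_map = NULL) {
  raw <- .trim_all(.read_raw_csv(path))
  cols <- .resolve_columns(names(raw), .reaction_columns, column_map)
  for (req in c("predecessor_cid", "successor_cid")) {
    if (is.na(cols[[req]])) {
      stop("reaction table schema error: no ", req, " column found.\n",
           "  headers present: ", paste(names(raw), collapse = ", "), "\n",
           "  expected one of: ",
           paste(.reaction_columns[[req]], collapse = ", "),
           " (or supply column_map)", call. = FALSE)
    }
  }
  n <- nrow(raw)
  get <- function(canon) {
    src <- cols[[canon]]
    if (is.na(src)) rep(NA_character_, n) else .na_if_empty(raw[[src]])
  }
  pc <- .parse_cid(if (n) raw[[cols[["predecessor_cid"]]]] else character(0))
  sc <- .parse_cid(if (n) raw[[cols[["successor_cid"]]]] else character(0))
  out <- data.frame(
    predecessor_cid      = pc,
    successor_cid        = sc,
    predecessor_name     = get("predecessor_name"),
    successor_name       = get("successor_name"),
    reaction_smiles      = get("reaction_smiles"),
    desc_reaction_smiles = get("desc_reaction_smiles"),
    biosystem            = get("biosystem"),
    enzyme               = get("enzyme"),
    transformation       = get("transformation"),
    mass_diff            = .parse_num(get("mass_diff")),
    xlogp_diff           = .parse_num(get("xlogp_diff")),
    datasetref           = get("datasetref"),
    datasetdoi           = get("datasetdoi"),
    evidenceref          = get("evidenceref"),
    evidencedoi          = get("evidencedoi"),
    sourcecommentfull    = get("sourcecommentfull"),
    sourcecomment        = get("sourcecomment"),
    stringsAsFactors = FALSE
  )
  extra <- setdiff(names(raw), stats::na.omit(unname(cols)))
  for (e in extra) out[[e]] <- raw[[e]]

  bad <- which(is.na(pc) | is.na(sc))
  skipped <- data.frame(row = bad,
                        reason = rep("unparseable endpoint CID", length(bad)),
                        stringsAsFactors = FALSE)
  if (length(bad)) out <- out[-bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Read a community contribution template
#'
#' Parses a contribution template (predecessor/successor names and SMILES,
#' plus an optional biosystem column) into the reaction schema. CIDs are not
#' resolved: the `predecessor_cid`/`successor_cid` columns are `NA` and the
#' result carries attribute `cid_resolved = FALSE`. Extra columns (e.g. the
#' many condition fields of sludge/soil reporting templates) are passed
#' through unparsed. A row is rejected, with a reason in the `"rejected"`
#' attribute, when an endpoint has neither a name nor a SMILES.
#'
#' @param path Path to the template CSV.
#' @return A data frame in the reaction schema (CIDs `NA`), with attributes
#'   `cid_resolved` (always `FALSE`) and `rejected`.
#' @export
read_contribution_template <- function(path) {
  raw <- .trim_all(.read_raw_csv(path))
  tmpl_cols <- list(
    predecessor_name   = c("predecessor", "predecessorname", "parent", "parentname", "predecessor_name"),
    predecessor_smiles = c("predecessorsmiles", "parentsmiles", "predecessor_smiles", "smilesparent"),
    successor_name     = c("successor", "successorname", "tp", "tpname", "transformationproduct", "successor_name"),
    successor_smiles   = c("successorsmiles", "tpsmiles", "successor_smiles", "smilestp"),
    biosystem          = c("biosystem", "system", "matrix")
  )
  cols <- .resolve_columns(names(raw), tmpl_cols, NULL)
  n <- nrow(raw)
  get <- function(canon) {
    src <- cols[[canon]]
    if (is.na(src)) rep(NA_character_, n) else .na_if_empty(raw[[src]])
  }
  pn <- get("predecessor_name"); ps <- get("predecessor_smiles")
  sn <- get("successor_name");   ss <- get("successor_smiles")
  ok_pred <- !is.na(pn) | !is.na(ps)
  ok_succ <- !is.na(sn) | !is.na(ss)
  bad <- which(!(ok_pred & ok_succ))
  reason <- ifelse(!ok_pred[bad] & !ok_succ[bad],
                   "no name or SMILES for either endpoint",
                   ifelse(!ok_pred[bad], "no name or SMILES for predecessor",
                          "no name or SMILES for successor"))
  out <- data.frame(
    predecessor_cid      = rep(NA_integer_, n),
    successor_cid        = rep(NA_integer_, n),
    predecessor_name     = pn,
    successor_name       = sn,
    reaction_smiles      = ifelse(!is.na(ps) & !is.na(ss),
                                  paste0(ps, ">>", ss), NA_character_),
    desc_reaction_smiles = rep(NA_character_, n),
    predecessor_smiles   = ps,
    successor_smiles     = ss,
    biosystem            = get("biosystem"),
    enzyme               = rep(NA_character_, n),
    transformation       = rep(NA_character_, n),
    mass_diff            = rep(NA_real_, n),
    xlogp_diff           = rep(NA_real_, n),
    datasetref           = rep("contribution", n),
    stringsAsFactors = FALSE
  )
  extra <- setdiff(names(raw), stats::na.omit(unname(cols)))
  for (e in extra) out[[e]] <- raw[[e]]
  rejected <- data.frame(row = bad, reason = reason, stringsAsFactors = FALSE)
  if (length(bad)) out <- out[-bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cid_resolved") <- FALSE
  attr(out, "rejected") <- rejected
  out
}

# Canonical export headers. These are fixed contracts of the downstream
# suspect-screening tools and must never vary with the input.
.export_headers <- list(
  metfrag     = c("Identifier", "Name", "InChIKey", "InChI", "SMILES",
                  "MolecularFormula", "MonoisotopicMass"),
  patroon     = c("Name", "InChI", "SMILES", "Formula", "ExactMass"),
  generic_csv = c("CID", "Name", "SMILES", "InChI", "InChIKey", "IKFB",
                  "MolecularFormula", "ExactMass", "XlogP", "IUPACName",
                  "Title"),
  xlsx        = c("CID", "Name", "SMILES", "InChI", "InChIKey", "IKFB",
                  "MolecularFormula", "ExactMass", "XlogP", "IUPACName",
                  "Title")
)

#' Canonical export column header for a format
#'
#' @param format One of `"metfrag"`, `"patroon"`, `"generic_csv"`, `"xlsx"`.
#' @return Character vector of column names, in order.
#' @export
export_header <- function(format) {
  if (!format %in% names(.export_headers)) {
    stop("unknown export format: '", format, "' (expected one of ",
         paste(names(.export_headers), collapse = ", "), ")", call. = FALSE)
  }
  .export_headers[[format]]
}

.export_name <- function(compounds) {
  nm <- if ("display_name" %in% names(compounds)) compounds$display_name
        else rep(NA_character_, nrow(compounds))
  nm <- ifelse(is.na(nm) & !is.na(compounds$title), compounds$title, nm)
  nm <- ifelse(is.na(nm) & !is.na(compounds$iupac_name), compounds$iupac_name, nm)
  ifelse(is.na(nm), paste("CID", compounds$cid), nm)
}

#' Export compounds as a suspect list
#'
#' Builds an export table from compound records. The `metfrag` format has
#' exactly the columns `Identifier, Name, InChIKey, InChI, SMILES,
#' MolecularFormula, MonoisotopicMass`; the `patroon` format has exactly
#' `Name, InChI, SMILES, Formula, ExactMass`. `Identifier`/`CID` carries the
#' compound CID and `Name` the display name (falling back to title, IUPAC
#' name, then "CID n"). `generic_csv` and `xlsx` carry the full compound
#' schema. When `path` is given the table is also serialized: CSV formats via
#' [utils::write.csv()]; `xlsx` through a helper invoking Python's openpyxl.
#'
#' @param compounds Compound data frame ([read_compound_table()] schema,
#'   optionally with a `display_name` column).
#' @param format One of `"metfrag"`, `"patroon"`, `"generic_csv"`, `"xlsx"`.
#' @param path Optional output file path.
#' @return An object of class `tp_export`: list with `format`, `header`,
#'   `table` (data frame) and `path` (or `NA`).
#' @export
write_export <- function(compounds, format, path = NULL) {
  header <- export_header(format)
  if (is.null(compounds)) stop("compounds must not be NULL", call. = FALSE)
  if (anyDuplicated(compounds$cid)) {
    stop("duplicated CID in export selection: ",
         paste(unique(compounds$cid[duplicated(compounds$cid)]), collapse = ", "),
         call. = FALSE)
  }
  nm <- if (nrow(compounds)) .export_name(compounds) else character(0)
  tab <- switch(format,
    metfrag = data.frame(
      Identifier = compounds$cid, Name = nm,
      InChIKey = compounds$inchikey, InChI = compounds$inchi,
      SMILES = compounds$smiles, MolecularFormula = compounds$formula,
      MonoisotopicMass = compounds$exact_mass,
      stringsAsFactors = FALSE, check.names = FALSE),
    patroon = data.frame(
      Name = nm, InChI = compounds$inchi, SMILES = compounds$smiles,
      Formula = compounds$formula, ExactMass = compounds$exact_mass,
      stringsAsFactors = FALSE, check.names = FALSE),
    data.frame(
      CID = compounds$cid, Name = nm, SMILES = compounds$smiles,
      InChI = compounds$inchi, InChIKey = compounds$inchikey,
      IKFB = compounds$ikfb, MolecularFormula = compounds$formula,
      ExactMass = compounds$exact_mass, XlogP = compounds$xlogp,
      IUPACName = compounds$iupac_name, Title = compounds$title,
      stringsAsFactors = FALSE, check.names = FALSE)
  )
  stopifnot(identical(names(tab), header))
  if (!is.null(path)) {
    if (format == "xlsx") {
      .write_xlsx(tab, path)
    } else {
      utils::write.csv(tab, path, row.names = FALSE, na = "")
    }
  }
  structure(list(format = format, header = header, table = tab,
                 path = if (is.null(path)) NA_character_ else path),
            class = "tp_export")
}

#' @export
print.tp_export <- function(x, ...) {
  cat("<tp_export> format:", x$format, "-", nrow(x$table), "rows\n")
  cat("  columns:", paste(x$header, collapse = ", "), "\n")
  if (!is.na(x$path)) cat("  written to:", x$path, "\n")
  invisible(x)
}

# XLSX serialization delegates to the Python openpyxl library through a
# generated script; the table travels as a temporary CSV.
.write_xlsx <- function(tab, path) {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) {
    stop("xlsx export requires a 'python' interpreter with openpyxl on PATH",
         call. = FALSE)
  }
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp), add = TRUE)
  utils::write.csv(tab, tmp, row.names = FALSE, na = "")
  script <- tempfile(fileext = ".py")
  on.exit(unlink(script), add = TRUE)
  writeLines(c(
    "import csv, sys",
    "from openpyxl import Workbook",
    "wb = Workbook(); ws = wb.active; ws.title = 'export'",
    "with open(sys.argv[1], newline='', encoding='utf-8') as fh:",
    "    for row in csv.reader(fh):",
    "        ws.append(row)",
    "wb.save(sys.argv[2])"
  ), script)
  status <- system2(py, c(script, tmp, path), stdout = TRUE, stderr = TRUE)
  if (!file.exists(path)) {
    stop("xlsx export failed: ", paste(status, collapse = "\n"), call. = FALSE)
  }
  invisible(path)
}

#' Read back a generic CSV export
#'
#' Inverse of `write_export(..., format = "generic_csv")`; used for
#' round-trip checks and for re-importing exported selections.
#'
#' @param path Path to a generic CSV export file.
#' @return A compound data frame in the [read_compound_table()] schema with a
#'   `display_name` column.
#' @export
read_export_csv <- function(path) {
  raw <- .read_raw_csv(path)
  stopifnot(identical(names(raw), .export_headers$generic_csv))
  out <- data.frame(
    cid        = .parse_cid(raw$CID),
    smiles     = .na_if_empty(raw$SMILES),
    inchi      = .na_if_empty(raw$InChI),
    inchikey   = .na_if_empty(raw$InChIKey),
    ikfb       = .na_if_empty(raw$IKFB),
    formula    = .na_if_empty(raw$MolecularFormula),
    exact_mass = .parse_num(raw$ExactMass),
    xlogp      = .parse_num(raw$XlogP),
    iupac_name = .na_if_empty(raw$IUPACName),
    title      = .na_if_empty(raw$Title),
    display_name = .na_if_empty(raw$Name),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write compound and reaction tables in the source CSV schemas
#'
#' Serializes canonical compound/reaction data frames back to CSV files using
#' the default source header spellings, so that generated tables can be
#' re-read with [read_compound_table()] and [read_reaction_table()].
#'
#' @param compounds Compound data frame.
#' @param reactions Reaction data frame.
#' @param dir Output directory (created if missing).
#' @param compound_file,reaction_file File names within `dir`.
#' @return Invisibly, the two file paths.
#' @export
write_source_tables <- function(compounds, reactions, dir,
                                compound_file = "Transformations_CID_Info_all.csv",
                                reaction_file = "PubChem_all_transformations_wExtraInfo.csv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cpath <- file.path(dir, compound_file)
  rpath <- file.path(dir, reaction_file)
  cout <- data.frame(
    CID = compounds$cid, SMILES = compounds$smiles, InChI = compounds$inchi,
    InChIKey = compounds$inchikey, IKFB = compounds$ikfb,
    MolecularFormula = compounds$formula, ExactMass = compounds$exact_mass,
    XlogP = compounds$xlogp, IUPACName = compounds$iupac_name,
    Title = compounds$title, stringsAsFactors = FALSE, check.names = FALSE)
  rout <- data.frame(
    predecessorcid = reactions$predecessor_cid,
    successorcid = reactions$successor_cid,
    predecessor = reactions$predecessor_name,
    successor = reactions$successor_name,
    ReactionSMILES = reactions$reaction_smiles,
    DescReactionSMILES = reactions$desc_reaction_smiles,
    biosystem = reactions$biosystem, enzyme = reactions$enzyme,
    transformation = reactions$transformation,
    MassDiff = reactions$mass_diff, XlogPDiff = reactions$xlogp_diff,
    datasetref = reactions$datasetref, datasetdoi = reactions$datasetdoi,
    evidenceref = reactions$evidenceref, evidencedoi = reactions$evidencedoi,
    sourcecommentfull = reactions$sourcecommentfull,
    sourcecomment = reactions$sourcecomment,
    stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.csv(cout, cpath, row.names = FALSE, na = "")
  utils::write.csv(rout, rpath, row.names = FALSE, na = "")
  invisible(c(compounds = cpath, reactions = rpath))
}
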