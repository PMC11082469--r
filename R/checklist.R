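#' Column mapping for a checklist file
#'
#' Names the columns of a WCVP-style checklist export that carry the taxon
#' name, the acceptance status, the authorship string and the
#' first-publication field, plus the status value that marks an accepted
#' name. The defaults match a WCVP names export.
#'
#' @param taxon_col,status_col,author_col,year_col Column names in the file
#'   header.
#' @param accepted_value Status value (case-insensitive) identifying accepted
#'   species.
#' @return A named list of class `checklist_mapping`.
#' @export
checklist_mapping <- function(taxon_col = "taxon_name",
                              status_col = "taxon_status",
                              author_col = "taxon_authors",
                              year_col = "first_published",
                              accepted_value = "Accepted") {
  structure(list(taxon_col = taxon_col, status_col = status_col,
                 author_col = author_col, year_col = year_col,
                 accepted_value = accepted_value),
            class = "checklist_mapping")
}

#' Read a column mapping from a JSON or YAML config file
#'
#' The file may define any subset of the keys `taxon_col`, `status_col`,
#' `author_col`, `year_col`, `accepted_value`; unspecified keys keep the
#' [checklist_mapping()] defaults.
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return A `checklist_mapping`.
#' @export
read_mapping_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(checklist_mapping))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown mapping keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(checklist_mapping, cfg)
}

detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  cand <- c("\t", ",", "|")
  hits <- vapply(cand, function(d) {
    lengths(regmatches(header, gregexpr(d, header, fixed = TRUE)))
  }, integer(1))
  if (all(hits == 0)) "," else cand[which.max(hits)]
}

extract_year <- function(x) {
  # first 4-digit run; WCVP prints the year in parentheses, e.g. "(1753)"
  m <- regmatches(x, regexpr("[0-9]{4}", x))
  year <- suppressWarnings(as.integer(m))
  out <- rep(NA_integer_, length(x))
  out[regexpr("[0-9]{4}", x) > 0] <- year
  now <- as.integer(format(Sys.Date(), "%Y"))
  out[!is.na(out) & (out < 1000L | out > now)] <- NA_integer_
  out
}

#' Parse a checklist file into description records
#'
#' Reads a delimited checklist export (tab, comma or pipe; auto-detected from
#' the header) and returns one record per row with the taxon name, a
#' normalized acceptance status, the raw authorship string, and the first
#' 4-digit year extracted from the first-publication field. Rows with no
#' parseable year are retained with a missing year and filtered only at
#' tallying time. Row order is preserved.
#'
#' @param path Path to the checklist file (UTF-8).
#' @param mapping A [checklist_mapping()] naming the relevant columns.
#' @param delimiter Field delimiter; `NULL` (default) auto-detects among
#'   tab, comma and pipe.
#' @return A `data.frame` with columns `taxon_name`, `status` (factor
#'   `accepted`/`other`), `authorship`, `publication_year` (integer, `NA` if
#'   unparseable).
#' @export
parse_checklist <- function(path, mapping = checklist_mapping(),
                            delimiter = NULL) {
  if (!file.exists(path)) stop("checklist file not found: ", path,
                               call. = FALSE)
  if (is.null(delimiter)) delimiter <- detect_delimiter(path)
  raw <- utils::read.delim(path, sep = delimiter, header = TRUE,
                           quote = "\"", colClasses = "character",
                           check.names = FALSE, encoding = "UTF-8",
                           blank.lines.skip = FALSE)
  needed <- c(mapping$taxon_col, mapping$status_col,
              mapping$author_col, mapping$year_col)
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop("checklist is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  status <- ifelse(tolower(raw[[mapping$status_col]]) ==
                     tolower(mapping$accepted_value), "accepted", "other")
  data.frame(
    taxon_name = raw[[mapping$taxon_col]],
    status = factor(status, levels = c("accepted", "other")),
    authorship = raw[[mapping$author_col]],
    publication_year = extract_year(raw[[mapping$year_col]]),
    stringsAsFactors = FALSE
  )
}

#' Extract describing-author tokens from a taxonomic authority string
#'
#' Resolves a botanical authority string to the set of standard author
#' abbreviations credited with describing the taxon, following the usual
#' citation conventions:
#' \itemize{
#'   \item `"A ex B"` — B validated and published the name; B is credited.
#'   \item `"A in B"` — A authored the description inside B's work; A is
#'     credited.
#'   \item `"(X) Y"` — a new combination: X originally described the species
#'     (basionym authors). By default X is credited, since the modelled
#'     quantity is describing effort; set `credit = "combining"` to credit Y
#'     instead.
#'   \item `"A & B"`, `"A, B"` — all listed authors are credited.
#' }
#'
#' @param authorship Authority string (may be empty or `NA`).
#' @param credit For combinations `"(X) Y"`: `"basionym"` (default) credits
#'   X, `"combining"` credits Y.
#' @return Character vector of unique author tokens (empty if none parsed).
#' @examples
#' extract_authors("Hook.f. & Thomson")
#' extract_authors("Hook. ex Benth.")
#' extract_authors("(L.) Kuntze")
#' @export
extract_authors <- function(authorship,
                            credit = c("basionym", "combining")) {
  credit <- match.arg(credit)
  if (length(authorship) != 1) {
    stop("`authorship` must be a single string", call. = FALSE)
  }
  s <- trimws(as.character(authorship))
  if (is.na(s) || !nzchar(s)) return(character(0))
  # combination "(X) Y": keep the chosen side
  m <- regmatches(s, regexec("^\\(([^)]*)\\)\\s*(.*)$", s))[[1]]
  if (length(m) == 3) {
    s <- trimws(if (credit == "basionym") m[2] else m[3])
    if (!nzchar(s)) return(character(0))
  }
  # "A ex B": the validating author B is credited
  if (grepl("\\sex\\s", s)) {
    parts <- strsplit(s, "\\sex\\s")[[1]]
    s <- trimws(parts[length(parts)])
  }
  # "A in B": the describing author A is credited
  if (grepl("\\sin\\s", s)) {
    s <- trimws(strsplit(s, "\\sin\\s")[[1]][1])
  }
  tokens <- trimws(strsplit(s, "\\s*(&|,)\\s*")[[1]])
  unique(tokens[nzchar(tokens)])
}

is_infraspecific <- function(taxon_name) {
  grepl("\\s(subsp|ssp|var|subvar|f|forma)\\.(\\s|$)", taxon_name)
}

#' Tally per-year description and author counts
#'
#' Builds the two per-year series the models consume from a set of checklist
#' records: for each calendar year of the span, the number of accepted
#' species whose original description was published that year, and the number
#' of unique author tokens credited across those descriptions (the union of
#' per-species author sets). Years with no parsed authors are floored at 0.1
#' so the author series can enter the models as a logged offset.
#'
#' Records are filtered to accepted status and to years within the span;
#' infraspecific taxa are excluded by default; exact duplicates on
#' name + authorship are dropped (with a message).
#'
#' @param records Data frame from [parse_checklist()].
#' @param span Length-2 integer vector `c(start, end)` of calendar years.
#' @param exclude_infraspecific Drop taxa whose name carries an infraspecific
#'   rank marker (`subsp.`, `var.`, `f.`, ...). Default `TRUE`.
#' @param credit Author-credit convention passed to [extract_authors()].
#' @return A [yearly_series()].
#' @export
tally_series <- function(records, span, exclude_infraspecific = TRUE,
                         credit = c("basionym", "combining")) {
  credit <- match.arg(credit)
  stopifnot(length(span) == 2)
  span <- as.integer(span)
  if (span[1] > span[2]) stop("span start must not exceed end", call. = FALSE)

  keep <- records$status == "accepted" &
    !is.na(records$publication_year) &
    records$publication_year >= span[1] &
    records$publication_year <= span[2]
  if (exclude_infraspecific) keep <- keep & !is_infraspecific(records$taxon_name)
  rec <- records[keep, , drop = FALSE]

  dup <- duplicated(paste(rec$taxon_name, rec$authorship, sep = "\r"))
  if (any(dup)) {
    message(sum(dup), " duplicate name+authorship record(s) removed")
    rec <- rec[!dup, , drop = FALSE]
  }
  if (nrow(rec) == 0) {
    warning("no accepted in-span records; series is all zeros", call. = FALSE)
  }

  years <- span[1]:span[2]
  counts <- integer(length(years))
  authors <- numeric(length(years))
  tab <- table(factor(rec$publication_year, levels = years))
  counts <- as.integer(tab)
  for (i in seq_along(years)) {
    rows <- which(rec$publication_year == years[i])
    toks <- unique(unlist(lapply(rec$authorship[rows], extract_authors,
                                 credit = credit)))
    authors[i] <- length(toks)
  }
  authors[authors == 0] <- 0.1
  yearly_series(years, counts, authors)
}
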