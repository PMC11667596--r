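# Reading, validating and writing the MAUDE pipe-delimited flat-file dialect.
#
# A MAUDE extract ships as three files joined on MDR_REPORT_KEY: the master
# event file (one row per report: event type and dates), the device file
# (one row per reported device: FDA product code, brand, manufacturer) and
# the narrative ("foitext") file (one row per free-text block).

# Default column layouts; names are the internal field names, values the
# header names used in public MAUDE exports. Override via `col_map`.
maude_layouts <- function() {
  list(
    master = c(
      report_key      = "MDR_REPORT_KEY",
      event_type_code = "EVENT_TYPE",
      date_of_event   = "DATE_OF_EVENT",
      date_received   = "DATE_RECEIVED"
    ),
    device = c(
      report_key   = "MDR_REPORT_KEY",
      product_code = "DEVICE_REPORT_PRODUCT_CODE",
      brand_name   = "BRAND_NAME",
      manufacturer = "MANUFACTURER_D_NAME"
    ),
    narrative = c(
      report_key     = "MDR_REPORT_KEY",
      text_key       = "MDR_TEXT_KEY",
      text_type_code = "TEXT_TYPE_CODE",
      text           = "FOI_TEXT"
    )
  )
}

#' Parse a MAUDE date token
#'
#' MAUDE extracts carry dates either as `MM/DD/YYYY` or as 8-digit `YYYYMMDD`;
#' both dialects are auto-detected per token (the two forms cannot be
#' confused). Empty or whitespace-only tokens are missing. Tokens in either
#' form that do not name a real calendar day (e.g. `02/30/2015`), and tokens
#' in any other shape, map to missing with a warning — the function is total
#' and never errors.
#'
#' @param x Character vector of raw field values.
#' @return A `Date` vector of the same length, `NA` where missing/invalid.
#' @export
#' @examples
#' parse_maude_date(c("01/15/2013", "20200229", ""))
parse_maude_date <- function(x) {
  x <- trimws(ifelse(is.na(x), "", as.character(x)))
  out <- rep(as.Date(NA), length(x))
  slash <- grepl("^[0-9]{1,2}/[0-9]{1,2}/[0-9]{4}$", x)
  plain <- grepl("^[0-9]{8}$", x)
  out[slash] <- as.Date(x[slash], format = "%m/%d/%Y")
  out[plain] <- as.Date(x[plain], format = "%Y%m%d")
  bad <- nzchar(x) & is.na(out)
  if (any(bad)) {
    warning(sum(bad), " date token(s) unparseable or not a real calendar day; ",
            "treated as missing", call. = FALSE)
  }
  out
}

#' Read one MAUDE-style flat file
#'
#' Parses a pipe-delimited, header-first text file in one of the three MAUDE
#' layouts. Fields may be wrapped in double quotes; embedded pipes (and
#' doubled quotes) inside quoted fields are preserved. A data row is malformed
#' when its field count disagrees with the header or a required identifier
#' field is empty (for device rows, also when the product code is not a
#' 3-character uppercase alphanumeric code). In lenient mode (the default)
#' malformed rows are skipped and counted; in strict mode the first one
#' aborts with its row number.
#'
#' @param path Path to the file.
#' @param layout One of `"master"`, `"device"`, `"narrative"`.
#' @param strict Abort on the first malformed row instead of skipping?
#' @param col_map Optional named character vector renaming layout columns,
#'   e.g. `c(report_key = "REPORT_ID")`.
#' @param quiet Suppress the `skipped=<n>` log message?
#' @return A `data.frame` with the layout's internal column names (dates in
#'   the master layout are parsed to `Date`), plus attributes `skipped`
#'   (malformed row count) and `source_file`.
#' @export
read_maude_file <- function(path, layout = c("master", "device", "narrative"),
                            strict = FALSE, col_map = NULL, quiet = TRUE) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cols <- maude_layouts()[[layout]]
  if (!is.null(col_map)) {
    unknown <- setdiff(names(col_map), names(cols))
    if (length(unknown)) {
      stop("unknown layout field(s) in col_map: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cols[names(col_map)] <- col_map
  }

  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines) || !nzchar(trimws(lines[1]))) {
    stop("no header row in ", path, call. = FALSE)
  }
  header <- scan(text = lines[1], what = character(), sep = "|", quote = "\"",
                 quiet = TRUE)
  missing_cols <- setdiff(unname(cols), header)
  if (length(missing_cols)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  body <- lines[-1]
  keep_line <- nzchar(trimws(body))
  body <- body[keep_line]
  row_no <- which(keep_line) + 1L  # 1-based file line numbers

  bad <- logical(length(body))
  if (length(body)) {
    nf <- utils::count.fields(textConnection(body), sep = "|", quote = "\"",
                              comment.char = "", blank.lines.skip = FALSE)
    bad <- is.na(nf) | nf != length(header)
  }

  parse_rows <- function(rows) {
    if (!length(rows)) {
      df <- as.data.frame(matrix(character(0), ncol = length(header)),
                          stringsAsFactors = FALSE)
    } else {
      df <- utils::read.table(text = paste(rows, collapse = "\n"), sep = "|",
                              quote = "\"", header = FALSE,
                              colClasses = "character", comment.char = "",
                              stringsAsFactors = FALSE)
    }
    names(df) <- header
    df <- df[, unname(cols), drop = FALSE]
    names(df) <- names(cols)
    df
  }

  df <- parse_rows(body[!bad])
  row_no_ok <- row_no[!bad]

  # Required-field validation on parsed rows.
  invalid <- !nzchar(trimws(df$report_key))
  if (layout == "device") {
    invalid <- invalid | !grepl("^[A-Z0-9]{3}$", trimws(df$product_code))
  }
  if (layout == "narrative") {
    invalid <- invalid | !nzchar(trimws(df$text_key))
  }

  if (strict && (any(bad) || any(invalid))) {
    first <- min(c(row_no[bad], row_no_ok[invalid]))
    stop("malformed row at line ", first, " of ", path, call. = FALSE)
  }
  skipped <- sum(bad) + sum(invalid)
  df <- df[!invalid, , drop = FALSE]
  rownames(df) <- NULL

  if (layout == "master") {
    df$event_date <- parse_maude_date(df$date_of_event)
    df$received_date <- parse_maude_date(df$date_received)
    df$date_of_event <- NULL
    df$date_received <- NULL
  }
  if (layout == "device") df$product_code <- trimws(df$product_code)
  df$report_key <- trimws(df$report_key)

  if (!quiet) message("read ", basename(path), ": rows=", nrow(df),
                      " skipped=", skipped)
  attr(df, "skipped") <- skipped
  attr(df, "source_file") <- basename(path)
  df
}

#' Write one MAUDE-style flat file
#'
#' Inverse of [read_maude_file()]: writes a data frame with the layout's
#' internal column names as a pipe-delimited file with the layout's header.
#' Every field is double-quoted (embedded quotes doubled), so embedded pipes
#' survive a round trip; dates are written as `MM/DD/YYYY` and missing values
#' as empty fields.
#'
#' @inheritParams read_maude_file
#' @param x Data frame with the layout's internal columns.
#' @return `path`, invisibly.
#' @export
write_maude_file <- function(x, path, layout = c("master", "device", "narrative"),
                             col_map = NULL) {
  layout <- match.arg(layout)
  cols <- maude_layouts()[[layout]]
  if (!is.null(col_map)) cols[names(col_map)] <- col_map

  if (layout == "master") {
    x <- data.frame(
      report_key      = x$report_key,
      event_type_code = x$event_type_code,
      date_of_event   = ifelse(is.na(x$event_date), "",
                               format(x$event_date, "%m/%d/%Y")),
      date_received   = ifelse(is.na(x$received_date), "",
                               format(x$received_date, "%m/%d/%Y")),
      stringsAsFactors = FALSE
    )
  }
  missing_cols <- setdiff(names(cols), names(x))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- x[, names(cols), drop = FALSE]
  names(out) <- unname(cols)
  utils::write.table(out, path, sep = "|", quote = TRUE, qmethod = "double",
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Join the three MAUDE layouts into assembled reports
#'
#' Produces one assembled report per distinct report key in the master file:
#' the master fields, the de-duplicated set of product codes attached to the
#' key, and the narrative blocks attached to the key in text-key order.
#' When several master rows share a key, the one with the latest received
#' date is kept (ties and all-missing dates: first encountered) and the rest
#' are counted as duplicate master rows. Device or narrative rows whose key
#' never appears in the master file are orphans: they are dropped and counted,
#' never an error, because real extracts contain them.
#'
#' @param masters,devices,narratives Data frames from [read_maude_file()];
#'   `devices` and `narratives` may be `NULL`.
#' @param quiet Suppress the `orphans=` log message?
#' @return A `data.frame` with columns `report_key`, `event_type_code`,
#'   `event_date`, `received_date` and list-columns `product_codes` (sorted
#'   unique codes) and `narratives` (text blocks in text-key order), plus
#'   attributes `orphans` (named count: device, narrative) and
#'   `duplicate_master_rows`.
#' @export
assemble_reports <- function(masters, devices = NULL, narratives = NULL,
                             quiet = TRUE) {
  keys <- masters$report_key
  ukeys <- unique(keys)

  # One master row per key: latest received_date wins, first encountered on tie.
  if (anyDuplicated(keys)) {
    recv <- as.numeric(masters$received_date)
    recv[is.na(recv)] <- -Inf
    pick <- vapply(split(seq_along(keys), factor(keys, levels = ukeys)),
                   function(i) i[which.max(recv[i])], integer(1))
  } else {
    pick <- seq_along(keys)
  }
  dup_masters <- length(keys) - length(ukeys)

  empty_chr <- stats::setNames(rep(list(character(0)), length(ukeys)), ukeys)
  orphans <- c(device = 0L, narrative = 0L)

  codes_by_key <- empty_chr
  if (!is.null(devices) && nrow(devices)) {
    orphan <- !(devices$report_key %in% ukeys)
    orphans["device"] <- sum(orphan)
    d <- devices[!orphan, , drop = FALSE]
    codes_by_key <- lapply(
      split(d$product_code, factor(d$report_key, levels = ukeys)),
      function(z) sort(unique(z))
    )
  }

  texts_by_key <- empty_chr
  if (!is.null(narratives) && nrow(narratives)) {
    orphan <- !(narratives$report_key %in% ukeys)
    orphans["narrative"] <- sum(orphan)
    n <- narratives[!orphan, , drop = FALSE]
    n <- n[order(n$text_key), , drop = FALSE]  # stable: text_key order per key
    texts_by_key <- split(n$text, factor(n$report_key, levels = ukeys))
  }

  out <- data.frame(report_key = ukeys, stringsAsFactors = FALSE)
  out$event_type_code <- masters$event_type_code[pick]
  out$event_date <- masters$event_date[pick]
  out$received_date <- masters$received_date[pick]
  out$product_codes <- I(unname(codes_by_key))
  out$narratives <- I(unname(texts_by_key))

  if (!quiet) message("assembled ", nrow(out), " reports; orphans=",
                      sum(orphans), " duplicate_master_rows=", dup_masters)
  attr(out, "orphans") <- orphans
  attr(out, "duplicate_master_rows") <- dup_masters
  out
}
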