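# Participant CSV format, validation against the data dictionary, and
# the end-to-end pipeline runner.

#' Data dictionary for the participant CSV
#'
#' One row per column of the participant file: name, storage type,
#' allowed codes and a short description. Washington Group responses are
#' coded 0 (no difficulty) to 3 (cannot do); participation items 1 (no
#' difficulty) to 4 (inability to perform); missing values are empty
#' cells.
#'
#' @return Data frame with columns `column`, `type`, `allowed`,
#'   `description`.
#' @export
data_dictionary <- function() {
  row <- function(column, type, allowed, description) {
    data.frame(column = column, type = type, allowed = allowed,
               description = description, stringsAsFactors = FALSE)
  }
  base <- rbind(
    row("id", "character", "", "participant identifier"),
    row("cluster_id", "integer", "1:", "survey cluster"),
    row("country", "character", "cameroon|india", "study setting"),
    row("age", "integer", "0:130", "age in completed years"),
    row("sex", "character", "male|female", "sex"),
    row("respondent_type", "character", "self|caregiver|proxy",
        "who answered the self-report module")
  )
  wg <- do.call(rbind, lapply(wg_all_domains(), function(d) {
    row(paste0("wg_", d), "integer", "0:3",
        paste("reported difficulty,", gsub("_", " ", d)))
  }))
  clin <- rbind(
    row("va_denominator", "numeric", ">0", "Snellen denominator x in 6/x (ages 5+)"),
    row("fix_and_follow", "logical", "", "infant vision screen (age < 2)"),
    row("counts_fingers", "logical", "", "toddler vision screen (ages 2-4)"),
    row("oae_pass_left", "logical", "", "oto-acoustic emissions pass, left ear"),
    row("oae_pass_right", "logical", "", "oto-acoustic emissions pass, right ear"),
    row("pta_better_ear", "numeric", ">=0", "pure-tone average, better ear (dBA)"),
    row("msi_screen_positive", "logical", "", "musculoskeletal screen"),
    row("msi_exam_grade", "character", "none|mild|moderate|severe",
        "physiotherapist exam grade"),
    row("gtc_seizures_12m", "integer", "0:",
        "generalised tonic-clonic seizures, past 12 months")
  )
  phq <- do.call(rbind, lapply(1:9, function(j) {
    row(paste0("phq9_", j), "integer", "0:3", paste("PHQ-9 item", j))
  }))
  rest <- rbind(
    row("phq9_administered_full", "logical", "", "were PHQ-9 items 4-9 administered"),
    row("single_question_disability", "logical", "",
        "direct single-question disability screen (India)")
  )
  part <- do.call(rbind, lapply(1:21, function(j) {
    row(paste0("part_", j), "integer", "1:4", paste("participation item", j))
  }))
  rbind(base, wg, clin, phq, rest, part)
}

#' Write a participant table to CSV
#'
#' @param records Participant data frame.
#' @param path Output file. Missing values are written as empty cells.
#' @export
write_participants <- function(records, path) {
  dict <- data_dictionary()
  missing_cols <- setdiff(dict$column, names(records))
  if (length(missing_cols)) {
    stop("records are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(records[, dict$column], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a participant CSV
#'
#' Reads a participant file, types every column per the data dictionary
#' and rejects unknown codes with a diagnostic naming the offending row
#' and column. A file whose header does not match the dictionary is a
#' schema error.
#'
#' @param path CSV file written by [write_participants()] or following
#'   the same dictionary.
#' @param dictionary Data dictionary, see [data_dictionary()].
#' @return Typed participant data frame.
#' @export
read_participants <- function(path, dictionary = data_dictionary()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  if (!identical(header, dictionary$column)) {
    stop("schema error: header does not match the data dictionary\n",
         "  missing: ", paste(setdiff(dictionary$column, header), collapse = ", "),
         "\n  unexpected: ", paste(setdiff(header, dictionary$column), collapse = ", "),
         call. = FALSE)
  }
  classes <- c(character = "character", integer = "integer",
               numeric = "numeric", logical = "logical")[dictionary$type]
  df <- utils::read.csv(path, colClasses = unname(classes), na.strings = "",
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(dictionary))) {
    col <- dictionary$column[i]
    allowed <- dictionary$allowed[i]
    x <- df[[col]]
    bad <- rep(FALSE, length(x))
    if (allowed == "") {
      # typed by read.csv already
    } else if (grepl("\\|", allowed)) {
      bad <- !is.na(x) & !(x %in% strsplit(allowed, "\\|")[[1]])
    } else if (grepl("^(-?[0-9]+)?:(-?[0-9]+)?$", allowed)) {
      bounds <- strsplit(allowed, ":")[[1]]
      lo <- if (bounds[1] == "") -Inf else as.numeric(bounds[1])
      hi <- if (length(bounds) < 2 || bounds[2] == "") Inf else as.numeric(bounds[2])
      bad <- !is.na(x) & (x < lo | x > hi)
    } else if (allowed == ">0") {
      bad <- !is.na(x) & x <= 0
    } else if (allowed == ">=0") {
      bad <- !is.na(x) & x < 0
    }
    if (any(bad)) {
      r <- which(bad)[1]
      stop(sprintf("invalid value '%s' in column '%s', row %d", x[r], col, r),
           call. = FALSE)
    }
  }
  df
}

# small stable fingerprint (multiplicative hash over the deparsed
# object) for run logs
#' @keywords internal
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 69069 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> screen/classify -> prevalence
#' estimation -> agreement analyses, writing one CSV per stage plus a
#' run log (software version, seed, config hash). Any stage failure
#' aborts with the stage name; outputs of completed stages are
#' preserved.
#'
#' @param config Path to a YAML configuration file, or an equivalent
#'   named list. Required keys: `country`, `seed`. Optional: `input`
#'   (an existing participant CSV; otherwise a cohort is simulated),
#'   `n_clusters`, `cluster_size`, `threshold` (`some`/`alot`),
#'   `min_domains`, and `overrides` (passed to [cohort_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the files written.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("country", "seed")
  missing_keys <- setdiff(required, names(config))
  if (length(missing_keys)) {
    stop("config validation error: missing key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  if (!config$country %in% c("cameroon", "india")) {
    stop("config validation error: country must be 'cameroon' or 'india'",
         call. = FALSE)
  }
  threshold <- switch(as.character(config$threshold %||% "alot"),
                      some = "some", alot = "a_lot",
                      stop("config validation error: threshold must be 'some' or 'alot'",
                           call. = FALSE))
  min_domains <- config$min_domains %||% 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  records <- stage("simulate", {
    if (!is.null(config$input)) {
      read_participants(config$input)
    } else {
      extra <- config$overrides %||% list()
      args <- c(list(country = config$country), extra)
      if (!is.null(config$n_clusters)) args$n_clusters <- as.integer(config$n_clusters)
      if (!is.null(config$cluster_size)) args$cluster_size <- as.integer(config$cluster_size)
      coh <- generate_cohort(do.call(cohort_config, args),
                             seed = as.integer(config$seed))
      files$cohort <- file.path(out_dir, "cohort.csv")
      write_participants(coh$records, files$cohort)
      coh$records
    }
  })

  classification <- stage("classify", {
    records <- screen_cohort(records)
    cc <- classify_cohort(records, threshold = threshold,
                          min_domains = min_domains)
    files$case_status <- file.path(out_dir, "case_status.csv")
    utils::write.csv(cc$status, files$case_status, row.names = FALSE, na = "")
    cc
  })
  records <- screen_cohort(records)

  stage("estimate", {
    st <- classification$status
    est <- estimate_prevalence(st$self_reported | st$clinical,
                               records$cluster_id)
    files$prevalence <- file.path(out_dir, "prevalence.csv")
    utils::write.csv(data.frame(measure = "overall_disability",
                                point = est$point, ci_low = est$ci_low,
                                ci_high = est$ci_high, n = est$n,
                                n_clusters = est$n_clusters, deff = est$deff),
                     files$prevalence, row.names = FALSE)
  })

  stage("agree", {
    ct <- matched_domain_crosstab(records)
    files$crosstab <- file.path(out_dir, "crosstab.csv")
    utils::write.csv(cbind(reported = rownames(ct$counts),
                           as.data.frame(ct$counts),
                           as.data.frame(ct$row_pct) |>
                             stats::setNames(paste0(colnames(ct$counts), "_pct"))),
                     files$crosstab, row.names = FALSE)
    reg <- concordance_regression(records, classification)
    files$regression <- file.path(out_dir, "regression.csv")
    utils::write.csv(reg, files$regression, row.names = FALSE)
    pp <- participation_comparison(records, classification)
    files$participation <- file.path(out_dir, "participation.csv")
    utils::write.csv(pp$summary, files$participation, row.names = FALSE)
    sw <- definition_sweep(records)
    files$sweep <- file.path(out_dir, "sweep.csv")
    utils::write.csv(sw, files$sweep, row.names = FALSE)
  })

  stage("report", {
    files$log <- file.path(out_dir, "log.txt")
    writeLines(c(
      paste("icfsurvey version:", as.character(utils::packageVersion("icfsurvey"))),
      paste("seed:", config$seed),
      paste("config hash:", config_hash(config)),
      paste("records:", nrow(records)),
      paste("written:", paste(basename(unlist(files)), collapse = ", "))
    ), files$log)
  })
  invisible(files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
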