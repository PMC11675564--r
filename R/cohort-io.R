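#' Write a cohort to CSV files
#'
#' Writes three files into `dir`: `samples.csv` in long format
#' (`mother_id`, `timepoint`, `analyte`, `concentration`, `qc_pass`; an
#' empty concentration cell marks a below-LOQ value), `mothers.csv`
#' (`mother_id`, `group`, `bmi`, `age`, `income`, `fetus_sex`,
#' `education`), and `loq.csv` (`analyte`, `loq`).
#'
#' @param cohort An `scfa_cohort`.
#' @param dir Output directory (created if needed).
#' @return The three file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "scfa_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- cohort$samples
  long <- do.call(rbind, lapply(cohort$analytes, function(a) {
    data.frame(mother_id = s$mother_id, timepoint = s$timepoint,
               analyte = a, concentration = s[[a]], qc_pass = s$qc_pass,
               stringsAsFactors = FALSE)
  }))
  long <- long[order(long$mother_id, match(long$timepoint, cohort$timepoints),
                     match(long$analyte, cohort$analytes)), ]
  paths <- file.path(dir, c("samples.csv", "mothers.csv", "loq.csv"))
  utils::write.csv(long, paths[1], row.names = FALSE, na = "")
  utils::write.csv(cohort$mothers, paths[2], row.names = FALSE)
  utils::write.csv(data.frame(analyte = names(cohort$loq),
                              loq = unname(cohort$loq)),
                   paths[3], row.names = FALSE)
  invisible(paths)
}

#' Read a cohort from CSV files
#'
#' Reads the three files written by [write_cohort()] (or supplied by an
#' external assay pipeline in the same layout) and reconstructs an
#' `scfa_cohort`. Concentrations reported as empty cells or below the
#' analyte's LOQ are treated identically as the below-LOQ missing marker.
#' Categorical covariates are validated against the default level sets
#' when they match, otherwise levels are taken from the data.
#'
#' @param dir Directory containing `samples.csv`, `mothers.csv`, `loq.csv`.
#' @return An `scfa_cohort`.
#' @export
read_cohort <- function(dir) {
  long <- utils::read.csv(file.path(dir, "samples.csv"),
                          stringsAsFactors = FALSE)
  mothers <- utils::read.csv(file.path(dir, "mothers.csv"),
                             stringsAsFactors = FALSE)
  loq_df <- utils::read.csv(file.path(dir, "loq.csv"),
                            stringsAsFactors = FALSE)
  need <- c("mother_id", "timepoint", "analyte", "concentration", "qc_pass")
  if (!all(need %in% names(long)))
    stop("samples.csv must have columns: ", paste(need, collapse = ", "))
  loq <- stats::setNames(loq_df$loq, loq_df$analyte)
  analytes_here <- unique(long$analyte)
  .check_loq(analytes_here, loq)
  tps <- unique(long$timepoint)

  key <- paste(long$mother_id, long$timepoint, sep = "\r")
  if (anyDuplicated(paste(key, long$analyte, sep = "\r")))
    stop("duplicate (mother_id, timepoint, analyte) rows in samples.csv")
  samples <- unique(long[c("mother_id", "timepoint")])
  ukey <- paste(samples$mother_id, samples$timepoint, sep = "\r")
  for (a in analytes_here) {
    rows <- long[long$analyte == a, ]
    v <- rows$concentration[match(ukey, paste(rows$mother_id, rows$timepoint,
                                              sep = "\r"))]
    v[!is.na(v) & v < loq[[a]]] <- NA_real_  # "<LOQ" and absent are the same
    samples[[a]] <- v
  }
  samples$qc_pass <- as.logical(long$qc_pass[match(ukey, key)])

  cp <- default_covariate_params()
  mothers$group <- .as_covariate_factor(mothers$group, .groups, "group")
  mothers$income <- .level_factor(mothers$income, cp$income$levels, "income")
  mothers$fetus_sex <- .level_factor(mothers$fetus_sex,
                                     cp$fetus_sex$levels, "fetus_sex")
  mothers$education <- .level_factor(mothers$education,
                                     cp$education$levels, "education")
  orphan <- setdiff(samples$mother_id, mothers$mother_id)
  if (length(orphan))
    stop("samples reference unknown mother(s): ",
         paste(utils::head(orphan, 5), collapse = ", "))
  samples <- samples[order(match(samples$timepoint, tps),
                           samples$mother_id), ]
  rownames(samples) <- NULL
  structure(list(samples = samples, mothers = mothers, loq = loq,
                 analytes = analytes_here, timepoints = tps),
            class = "scfa_cohort")
}

# strict: every observed value must belong to the declared level set
.as_covariate_factor <- function(x, levels, name) {
  bad <- setdiff(unique(x[!is.na(x)]), levels)
  if (length(bad))
    stop("unknown ", name, " level(s): ", paste(bad, collapse = ", "))
  factor(x, levels = levels)
}

# use canonical ordering when the data matches it, else observed levels
.level_factor <- function(x, canonical, name) {
  vals <- unique(x[!is.na(x)])
  if (all(vals %in% canonical)) factor(x, levels = canonical)
  else factor(x, levels = sort(vals))
}

#' LOQ table of a cohort
#' @param cohort An `scfa_cohort`.
#' @return Data frame with columns `analyte` and `loq`.
#' @export
loq_table <- function(cohort) {
  data.frame(analyte = names(cohort$loq), loq = unname(cohort$loq),
             stringsAsFactors = FALSE)
}
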