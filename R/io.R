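# Plain-CSV serialization of crowd datasets (UTF-8, header row):
#   ground_truth.csv: image_id, task_size, true_count
#   ordinal.csv:      participant_id, image_id, rank_position
#   numerical.csv:    participant_id, image_id, estimate
#   participants.csv: participant_id, interface_condition, task_size

#' Write a crowd dataset to a directory of CSV files
#'
#' @param dataset a [crowd_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_crowd_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "crowd_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  u <- dataset$universe
  utils::write.csv(
    data.frame(image_id = u$alternatives,
               task_size = dataset$task_size,
               true_count = as.integer(u$true_counts[u$alternatives])),
    file.path(dir, "ground_truth.csv"), row.names = FALSE)
  ords <- do.call(rbind, lapply(dataset$records, function(r)
    data.frame(participant_id = r$participant_id,
               image_id = names(r$ordinal$positions),
               rank_position = as.integer(r$ordinal$positions))))
  utils::write.csv(ords, file.path(dir, "ordinal.csv"), row.names = FALSE)
  nums <- do.call(rbind, lapply(dataset$records, function(r)
    data.frame(participant_id = r$participant_id,
               image_id = names(r$numerical$estimates),
               estimate = as.numeric(r$numerical$estimates))))
  utils::write.csv(nums, file.path(dir, "numerical.csv"), row.names = FALSE)
  parts <- do.call(rbind, lapply(dataset$records, function(r)
    data.frame(participant_id = r$participant_id,
               interface_condition = r$interface_condition,
               task_size = r$task_size)))
  utils::write.csv(parts, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a crowd dataset from a directory of CSV files
#'
#' @param dir directory holding the four CSV files written by
#'   [write_crowd_dataset()].
#' @return A [crowd_dataset()].
#' @export
read_crowd_dataset <- function(dir) {
  gt <- utils::read.csv(file.path(dir, "ground_truth.csv"),
                        colClasses = c(image_id = "character"))
  ords <- utils::read.csv(file.path(dir, "ordinal.csv"),
                          colClasses = c(participant_id = "character",
                                         image_id = "character"))
  nums <- utils::read.csv(file.path(dir, "numerical.csv"),
                          colClasses = c(participant_id = "character",
                                         image_id = "character"))
  parts <- utils::read.csv(file.path(dir, "participants.csv"),
                           colClasses = c(participant_id = "character"))
  uni <- universe(gt$image_id,
                  stats::setNames(as.integer(gt$true_count), gt$image_id))
  records <- lapply(seq_len(nrow(parts)), function(k) {
    pid <- parts$participant_id[k]
    o <- ords[ords$participant_id == pid, ]
    nn <- nums[nums$participant_id == pid, ]
    participant_record(
      pid, parts$interface_condition[k], parts$task_size[k],
      ordinal_ballot(pid, stats::setNames(o$rank_position, o$image_id)),
      numerical_ballot(pid, stats::setNames(nn$estimate, nn$image_id)))
  })
  crowd_dataset(uni, records, unique(parts$task_size)[1])
}

#' Adapter stub for the study's deposited repository files
#'
#' The schema of the deposited study data is not documented; this adapter is
#' a placeholder that fails with a pointer to the expected CSV layout.
#'
#' @param dir directory with deposited files.
#' @export
read_deposited_dataset <- function(dir) {
  stop("read_deposited_dataset: the deposited data schema is not known; ",
       "convert the files to the ground_truth/ordinal/numerical/participants ",
       "CSV layout and use read_crowd_dataset()")
}
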