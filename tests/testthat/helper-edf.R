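# Independent minimal EDF writer, following the published header layout
# byte by byte; used to create read fixtures at test time. Data are written
# as one data record with identity digital-to-physical scaling, so integer
# sample matrices round-trip exactly.
writeMiniEDF <- function(path, mat, fs, labels = paste0("CH", seq_len(nrow(mat)))) {
  Q <- nrow(mat)
  T <- ncol(mat)
  stopifnot(all(mat == round(mat)), max(abs(mat)) <= 32767,
            T %% 1 == 0)
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, w) {
    s <- as.character(x)
    writeBin(charToRaw(formatC(s, width = -w)), con)
  }
  pad("0", 8)                      # version
  pad("test patient", 80)
  pad("test recording", 80)
  pad("01.01.20", 8)
  pad("00.00.00", 8)
  pad(256 + Q * 256, 8)            # header bytes
  pad("", 44)
  pad(1, 8)                        # number of data records
  pad(format(T / fs, digits = 6), 8)  # record duration (s)
  pad(Q, 4)
  for (lab in labels) pad(lab, 16)
  for (i in seq_len(Q)) pad("transducer", 80)
  for (i in seq_len(Q)) pad("uV", 8)
  for (i in seq_len(Q)) pad(-32768, 8)   # physical min
  for (i in seq_len(Q)) pad(32767, 8)    # physical max
  for (i in seq_len(Q)) pad(-32768, 8)   # digital min
  for (i in seq_len(Q)) pad(32767, 8)    # digital max
  for (i in seq_len(Q)) pad("", 80)      # prefiltering
  for (i in seq_len(Q)) pad(T, 8)        # samples per record
  for (i in seq_len(Q)) pad("", 32)      # reserved
  for (q in seq_len(Q))
    writeBin(as.integer(mat[q, ]), con, size = 2L, endian = "little")
  invisible(path)
}
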