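# Deposited coordinate files (PDB/mmCIF) are not redistributable inside the
# package and cannot be fetched in an offline environment.  Checks against
# printed structural measurements look for user-supplied copies under
# `deposited/` at the repository root (e.g. deposited/7TCI.cif) and fail
# with an explanatory message when the files are absent.
deposited_path <- function(name) {
  candidates <- c(file.path("deposited", name),
                  file.path("..", "..", "deposited", name),
                  file.path("..", "..", "..", "deposited", name))
  hit <- candidates[file.exists(candidates)]
  if (length(hit) > 0) hit[1] else NA_character_
}

fail_deposited <- function(id) {
  testthat::fail(sprintf(paste0(
    "deposited coordinate file %s is unavailable: this check needs the ",
    "published structure, which cannot be downloaded in an offline ",
    "environment. Place the file under deposited/ at the repository root ",
    "to run it."), id))
}
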