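.onLoad <- function(libname, pkgname) {
  register_module_entry("sf_p1_load", sf_p1_load)
  register_module_entry("sf_p1_image", sf_p1_image)
  register_module_entry("sf_p1_detect", sf_p1_detect)
  register_module_entry("sf_p2_reload", sf_p2_reload)
  register_module_entry("sf_p2_image", sf_p2_image)
  register_module_entry("sf_p2_stitch", sf_p2_stitch)
  invisible()
}
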