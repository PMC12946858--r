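# High-NA vectorial PSF with a Gibson-Lanni mismatched stack.
# All lengths in nm; keys mirror the run_config()/optical_setup()/
# sampling_grid() argument names.
na: 1.3
wavelength: 632
n_sample: 1.5
model: vectorial
parameterisation: cartesian
polarisation: circular
pupil_size: 257
out_size: 101
pixel_size: 20
z_planes: [-500, 0, 500]
gibson_lanni:
  n_s: 1.3
  n_i: 1.5
  n_g: 1.5
  t_s: 1000
  t_g: 170000
  t_i_star: 130000
  t_g_star: 170000
output_format: tiff
output_mode: amplitude
normalisation: max
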