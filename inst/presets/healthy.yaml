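# Healthy-retina synthetic cohort: dense, wide, tortuous vasculature with
# unshifted background chromaticity. Densities and widths are fixture
# conventions chosen to reproduce effect directions, not HRF measurements.
group_name: healthy
n_images: 15
image_size: [256, 256]
vessel_density: 0.12
root_count: 6
branch_prob: 0.015
width_mean: 3.0
width_sd: 0.6
tortuosity: 0.18
background_rgb_mean: [180, 95, 45]
background_rgb_sd: [10, 8, 6]
green_shift: 0
blue_shift: 0
noise_sd: 5
seed: 101
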