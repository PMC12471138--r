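# Pathological (glaucoma-like) synthetic cohort: sparser, thinner, less
# tortuous vasculature and a chromatic shift concentrated in the green and
# blue channels. Values are fixture conventions reproducing effect
# directions, not HRF measurements.
group_name: pathological
n_images: 15
image_size: [256, 256]
vessel_density: 0.07
root_count: 4
branch_prob: 0.008
width_mean: 2.0
width_sd: 0.4
tortuosity: 0.10
background_rgb_mean: [180, 95, 45]
background_rgb_sd: [10, 8, 6]
green_shift: -12
blue_shift: -10
noise_sd: 5
seed: 202
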