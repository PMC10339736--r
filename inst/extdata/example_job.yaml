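# Example dhipea job: iterative double-hybrid IP/EA on a synthetic reference.
method: adc2            # orbital_energies | cisd | adc2
channel: both           # ip | ea | both
n_states: 2
scales: [1.2, 0.5]      # (c_os, c_ss); or use `functional: PBE-QIDH`
conv_energy: 1.0e-6     # hartree
ea_sign: attachment     # attachment | ea
toy: {n_occ: 4, n_virt: 6, n_aux: 20, seed: 7}
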