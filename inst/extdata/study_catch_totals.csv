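site_id,x_m,y_m,sampling_year,n_ind_total,n_ind_pyro,n_ind_nonpyro,n_ind_sapro,n_sp_total,n_sp_pyro,n_sp_nonpyro,n_sp_sapro
pooled,0,0,2011,2220,60,227,67,169,13,22,34
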