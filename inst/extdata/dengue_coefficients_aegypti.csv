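function,term,value
biting_rate,form,briere
biting_rate,c,2.02e-4
biting_rate,tmin,13.35
biting_rate,tmax,40.08
prob_vector_to_human,form,briere
prob_vector_to_human,c,8.49e-4
prob_vector_to_human,tmin,17.05
prob_vector_to_human,tmax,35.83
prob_human_to_vector,form,briere
prob_human_to_vector,c,4.91e-4
prob_human_to_vector,tmin,12.22
prob_human_to_vector,tmax,37.46
lifespan,form,quadratic
lifespan,c,1.48e-1
lifespan,tmin,9.16
lifespan,tmax,37.73
pdr,form,briere
pdr,c,6.56e-5
pdr,tmin,10.68
pdr,tmax,45.90
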