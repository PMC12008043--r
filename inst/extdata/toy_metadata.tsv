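sample_id	site_id	lat	lon
tox01	S01	43.3563	-79.7809
tox02	S01	43.3563	-79.7809
tox03	S02	43.41085	-79.70817
tox04	S02	43.41085	-79.70817
tox05	S03	43.46539	-79.63545
tox06	S03	43.46539	-79.63545
tox07	S04	43.51994	-79.56272
tox08	S04	43.51994	-79.56272
tox09	S05	43.57448	-79.48999
tox10	S05	43.57448	-79.48999
tox11	S06	43.62903	-79.41726
tox12	S06	43.62903	-79.41726
tox13	S07	43.68357	-79.34454
tox14	S07	43.68357	-79.34454
tox15	S08	43.73812	-79.27181
tox16	S08	43.73812	-79.27181
tox17	S09	43.79266	-79.19908
tox18	S09	43.79266	-79.19908
tox19	S10	43.84721	-79.12635
tox20	S10	43.84721	-79.12635
tox21	S11	43.90175	-79.05363
tox22	S11	43.90175	-79.05363
tox23	S12	43.9563	-78.9809
tox24	S12	43.9563	-78.9809
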