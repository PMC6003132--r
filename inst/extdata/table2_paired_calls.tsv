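sample_id	urine_cia	tissue_cia
patient_01	negative	negative
patient_02	negative	negative
patient_03	negative	negative
patient_04	negative	positive
patient_05	negative	positive
patient_06	negative	positive
patient_07	negative	positive
patient_08	negative	positive
patient_09	positive	negative
patient_10	positive	negative
patient_11	positive	positive
patient_12	positive	positive
patient_13	positive	positive
patient_14	positive	positive
patient_15	positive	positive
patient_16	positive	positive
patient_17	positive	positive
patient_18	positive	positive
patient_19	positive	positive
patient_20	positive	positive
patient_21	positive	positive
patient_22	positive	positive
patient_23	positive	positive
patient_24	positive	positive
patient_25	positive	positive
patient_26	positive	positive
patient_27	positive	positive
patient_28	positive	positive
patient_29	positive	positive
patient_30	positive	positive
patient_31	positive	positive
patient_32	positive	positive
patient_33	positive	positive
patient_34	positive	positive
patient_35	positive	positive
patient_36	positive	positive
patient_37	positive	positive
patient_38	positive	positive
patient_39	positive	positive
patient_40	positive	positive
patient_41	positive	positive
patient_42	positive	positive
patient_43	positive	positive
patient_44	positive	positive
patient_45	positive	positive
patient_46	positive	positive
patient_47	positive	positive
patient_48	positive	positive
patient_49	positive	positive
patient_50	positive	positive
patient_51	positive	positive
patient_52	positive	positive
patient_53	positive	positive
patient_54	positive	positive
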