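sample_id	urine_cia	cytology
patient_01	negative	negative
patient_02	negative	negative
patient_03	negative	negative
patient_04	negative	negative
patient_05	negative	negative
patient_06	negative	negative
patient_07	negative	positive
patient_08	negative	positive
patient_09	negative	positive
patient_10	negative	positive
patient_11	negative	positive
patient_12	positive	negative
patient_13	positive	negative
patient_14	positive	negative
patient_15	positive	negative
patient_16	positive	negative
patient_17	positive	negative
patient_18	positive	negative
patient_19	positive	negative
patient_20	positive	negative
patient_21	positive	negative
patient_22	positive	negative
patient_23	positive	negative
patient_24	positive	negative
patient_25	positive	negative
patient_26	positive	negative
patient_27	positive	negative
patient_28	positive	negative
patient_29	positive	negative
patient_30	positive	negative
patient_31	positive	negative
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
patient_55	positive	positive
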