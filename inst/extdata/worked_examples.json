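{
  "schema_version": "1.0",
  "studies": [
    {
      "study_id": "alsem2013",
      "citation": "Alsem 2013",
      "items_available": true,
      "criteria_available": true,
      "groups": [
        {
          "diagnosis_label": "CP",
          "n": 92,
          "percent_female": 41.3,
          "first_wave_mean_age": 2.5,
          "followup_length": 2,
          "n_waves": 3,
          "wave_mean_ages": null,
          "functioning": {
            "category": "unknown",
            "mean_iq": null
          }
        }
      ],
      "outcomes": [
        {
          "instrument_name": "TNO-AZL Preschool Children Quality of Life Parent Form",
          "score_label": "Total",
          "score_level": "total",
          "construct": "Behaviour problems, sleeping problems, and anxiety",
          "informants": [
            "parent"
          ],
          "child_rated": false
        }
      ],
      "instruments": [
        {
          "name": "TNO-AZL Preschool Children Quality of Life Parent Form",
          "designed_for_ndd": "no",
          "adapted_for_ndd": "no",
          "adaptation_note": null
        }
      ],
      "overlaps": []
    },
    {
      "study_id": "anderson2011",
      "citation": "Anderson 2011",
      "items_available": true,
      "criteria_available": true,
      "groups": [
        {
          "diagnosis_label": "ASD",
          "n": 65,
          "percent_female": 10.77,
          "first_wave_mean_age": 9.75,
          "followup_length": 9,
          "n_waves": 17,
          "wave_mean_ages": null,
          "functioning": {
            "category": "moderate_severe_id",
            "mean_iq": 53
          }
        }
      ],
      "outcomes": [
        {
          "instrument_name": "Aberrant Behavior Checklist",
          "score_label": "Lethargy/Social withdrawal subscale",
          "score_level": "subscale",
          "construct": "Maladaptive behaviours",
          "informants": [
            "parent"
          ],
          "child_rated": false
        },
        {
          "instrument_name": "Aberrant Behavior Checklist",
          "score_label": "Hyperactivity subscale",
          "score_level": "subscale",
          "construct": "Maladaptive behaviours",
          "informants": [
            "parent"
          ],
          "child_rated": false
        },
        {
          "instrument_name": "Aberrant Behavior Checklist",
          "score_label": "Irritability subscale",
          "score_level": "subscale",
          "construct": "Maladaptive behaviours",
          "informants": [
            "parent"
          ],
          "child_rated": false
        }
      ],
      "instruments": [
        {
          "name": "Aberrant Behavior Checklist",
          "designed_for_ndd": "yes",
          "adapted_for_ndd": "no",
          "adaptation_note": null
        }
      ],
      "overlaps": [
        {
          "outcome_ref": "Lethargy/Social withdrawal subscale",
          "item_text": "Fixed facial expression(s)",
          "criterion_text": "a lack of facial expressions",
          "criterion_code": "ASD A3, DSM-5",
          "match_code": "verbatim",
          "addressed": "cant_tell"
        },
        {
          "outcome_ref": "Hyperactivity subscale",
          "item_text": "Pays no attention when spoken to",
          "criterion_text": "failure of normal back-and-forth conversation",
          "criterion_code": "ASD A1, DSM-5",
          "match_code": "concretisation",
          "addressed": "no"
        },
        {
          "outcome_ref": "Irritability subscale",
          "item_text": "Cries over minor things",
          "criterion_text": "extreme distress at small changes",
          "criterion_code": "ASD A3, DSM-5",
          "match_code": "concretisation",
          "addressed": "no"
        }
      ]
    },
    {
      "study_id": "auerbach2008",
      "citation": "Auerbach 2008",
      "items_available": true,
      "criteria_available": true,
      "groups": [
        {
          "diagnosis_label": "Dyscalculia",
          "n": 29,
          "percent_female": 51.72,
          "first_wave_mean_age": 11.1,
          "followup_length": 6,
          "n_waves": 3,
          "wave_mean_ages": null,
          "functioning": {
            "category": "no_id",
            "mean_iq": 99.1
          }
        },
        {
          "diagnosis_label": "Nonpersistent dyscalculia",
          "n": 29,
          "percent_female": 51.72,
          "first_wave_mean_age": 11.1,
          "followup_length": 6,
          "n_waves": 3,
          "wave_mean_ages": null,
          "functioning": {
            "category": "no_id",
            "mean_iq": 99.4
          }
        }
      ],
      "outcomes": [
        {
          "instrument_name": "Child Behavior Checklist",
          "score_label": "Total",
          "score_level": "total",
          "construct": "Behaviour problems",
          "informants": [
            "parent"
          ],
          "child_rated": false
        },
        {
          "instrument_name": "Child Behavior Checklist",
          "score_label": "Attention problems subscale",
          "score_level": "subscale",
          "construct": "Behaviour problems",
          "informants": [
            "parent"
          ],
          "child_rated": false
        }
      ],
      "instruments": [
        {
          "name": "Child Behavior Checklist",
          "designed_for_ndd": "no",
          "adapted_for_ndd": "no",
          "adaptation_note": null
        }
      ],
      "overlaps": [
        {
          "outcome_ref": "Total",
          "item_text": "Poor school work",
          "criterion_text": "Difficulties learning and using academic skills",
          "criterion_code": "SLD A, DSM-5",
          "match_code": "concretisation",
          "addressed": "no"
        },
        {
          "outcome_ref": "Attention problems subscale",
          "item_text": "Poor school work",
          "criterion_text": "Difficulties learning and using academic skills",
          "criterion_code": "SLD A, DSM-5",
          "match_code": "concretisation",
          "addressed": "no"
        }
      ]
    },
    {
      "study_id": "baribeau2021",
      "citation": "Baribeau 2021",
      "items_available": true,
      "criteria_available": true,
      "groups": [
        {
          "diagnosis_label": "ASD",
          "n": 421,
          "percent_female": 15.44,
          "first_wave_mean_age": 3.34,
          "followup_length": 7,
          "n_waves": 8,
          "wave_mean_ages": null,
          "functioning": {
            "category": "mild_id",
            "mean_iq": 58
          }
        }
      ],
      "outcomes": [
        {
          "instrument_name": "Child Behavior Checklist",
          "score_label": "Anxiety problems subscale",
          "score_level": "subscale",
          "construct": "Anxiety",
          "informants": [
            "parent"
          ],
          "child_rated": false
        }
      ],
      "instruments": [
        {
          "name": "Child Behavior Checklist",
          "designed_for_ndd": "no",
          "adapted_for_ndd": "no",
          "adaptation_note": null
        }
      ],
      "overlaps": []
    }
  ]
}
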