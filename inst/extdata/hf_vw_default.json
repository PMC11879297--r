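{
  "unit_costs": [
    {
      "label": "home_visit",
      "amount": 102,
      "currency_year": "2021/22",
      "source": "NHS Cost Collection"
    },
    {
      "label": "ed_attendance",
      "amount": 158,
      "currency_year": "2021/22",
      "source": "NHS Cost Collection"
    },
    {
      "label": "nhs111_contact",
      "amount": 11,
      "currency_year": "2021/22",
      "source": "literature"
    },
    {
      "label": "outpatient_appointment",
      "amount": 213,
      "currency_year": "2021/22",
      "source": "NHS Cost Collection"
    },
    {
      "label": "admission",
      "amount": 2587,
      "currency_year": "2021/22",
      "source": "NHS Cost Collection, NEL short+long stay, HF/shock HRGs"
    },
    {
      "label": "excess_bed_day",
      "amount": 338,
      "currency_year": "2021/22",
      "source": "NHS Cost Collection 2017/18 inflated via PSSRU index"
    },
    {
      "label": "home_monitoring",
      "amount": 34,
      "currency_year": "2021/22",
      "source": "service records"
    },
    {
      "label": "home_setup",
      "amount": 30,
      "currency_year": "2021/22",
      "source": "service records"
    },
    {
      "label": "poc_test",
      "amount": 24.5,
      "currency_year": "2021/22",
      "source": "package estimate: iSTAT cartridge + handling (synthetic)"
    }
  ],
  "staff_roles": [
    {
      "band": "nurse_band6",
      "annual_cost": 94733,
      "annual_hours": 1553
    },
    {
      "band": "consultant",
      "annual_cost": 274176,
      "annual_hours": 2142
    }
  ],
  "activities": [
    {
      "label": "home_visit",
      "duration": 45,
      "mix": null,
      "cost_per_minute": 1.02
    },
    {
      "label": "virtual_call",
      "duration": 10,
      "mix": null,
      "cost_per_minute": 1.79
    }
  ],
  "fixed_costs": {
    "vw_running_aggregate": 308113
  },
  "setup_costs": {
    "communications": 4685
  },
  "cohort": {
    "n_patients": 324,
    "observed_months": 6,
    "step_up_proportion": 0.449942017781214,
    "age": {
      "mean": 78,
      "sd": 10,
      "min": 40,
      "max": 100
    },
    "p_female": 0.45,
    "diagnosis": {
      "codes": ["I50.0", "I50.1", "I50.9"],
      "weights": [0.25, 0.15, 0.6]
    },
    "vw_rates": {
      "home_visits": 3.35511982570806,
      "calls": 7.82122905027933,
      "poc_tests": 4,
      "ed_probability": 0.0886075949367089,
      "readmission_probability": 0.126014688828759,
      "nhs111_contacts": 0.0909090909090909
    },
    "sc_rates": {
      "outpatient_appointments": 0.549295774647887,
      "ed_probability": 0.120253164556962,
      "readmission_probability": 0.214920757634325,
      "nhs111_contacts": 0.0909090909090909
    },
    "bed_days_saved_step_down": 3.00129736742527,
    "mean_vw_length_of_stay": 7,
    "rapid_visit_proportion": 0.2,
    "event_day_max": 45,
    "control_multiplier": 2,
    "control_age_shift": 2
  },
  "horizon_days": 30,
  "dsa_fraction": 0.15,
  "visit_costing": "microcosted"
}
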